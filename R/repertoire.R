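# Clonotype-diversity controls: richness, Shannon, inverse Simpson and
# Pielou evenness with optional Monte-Carlo rarefaction, bootstrap CIs and
# an equivalence-style comparison between arms — the check that rest acts
# population-wide rather than through clonal outgrowth.

#' Construct a clonotype table
#'
#' @param records Data frame with `clone_id`, `sample_id`, `count`
#'   (nonnegative integers; `(clone_id, sample_id)` unique).
#' @param samples Data frame with `sample_id`, `arm` (and optionally `day`).
#' @return A `clonotype_table` list.
#' @export
clonotype_table <- function(records, samples) {
  required <- c("clone_id", "sample_id", "count")
  missing <- setdiff(required, names(records))
  if (length(missing))
    stop("clonotype records missing column(s): ",
         paste(missing, collapse = ", "))
  if (any(records$count < 0) || any(records$count != round(records$count)))
    stop("counts must be nonnegative integers")
  if (anyDuplicated(records[c("clone_id", "sample_id")]))
    stop("(clone_id, sample_id) pairs must be unique")
  tot <- tapply(records$count, records$sample_id, sum)
  if (any(tot == 0))
    stop("sample(s) with no positive counts: ",
         paste(names(tot)[tot == 0], collapse = ", "))
  if (!all(unique(records$sample_id) %in% samples$sample_id))
    stop("records reference samples absent from the sample sheet")
  structure(list(records = records, samples = samples),
            class = "clonotype_table")
}

# Named count vector of one sample (positive counts only).
sample_counts <- function(tab, sample_id) {
  r <- tab$records[tab$records$sample_id == sample_id &
                     tab$records$count > 0, ]
  stats::setNames(r$count, r$clone_id)
}

# Core metrics on a count vector.
diversity_metrics <- function(counts) {
  counts <- counts[counts > 0]
  rich <- length(counts)
  h <- unname(vegan::diversity(counts, index = "shannon"))
  inv <- unname(vegan::diversity(counts, index = "invsimpson"))
  pielou <- if (rich > 1) h / log(rich) else NA_real_
  c(richness = rich, shannon = h, invsimpson = inv, pielou = pielou)
}

# Without-replacement subsample of a count vector to the given depth.
rarefy_counts <- function(counts, depth) {
  reads <- rep.int(seq_along(counts), counts)
  tab <- tabulate(reads[sample.int(length(reads), depth)],
                  nbins = length(counts))
  stats::setNames(tab, names(counts))
}

#' Per-sample clonotype diversity report
#'
#' Computes richness (clones with positive count), Shannon entropy (nats),
#' inverse Simpson and Pielou evenness (`H / ln richness`; `NA` for a
#' single clone) for every sample. With `rarefy_to` set, metrics are means
#' over `n_boot` without-replacement subsamples at that common depth and
#' the 2.5/97.5 percentiles of the subsample distribution give the CI;
#' otherwise metrics are computed on observed frequencies and the CI comes
#' from `n_boot` multinomial bootstrap resamples at the observed depth.
#'
#' @param tab A [clonotype_table()].
#' @param rarefy_to Common rarefaction depth, or `NULL` for none. Every
#'   sample must have total count `>= rarefy_to`.
#' @param n_boot Subsample / bootstrap replicates.
#' @param seed Integer seed.
#' @return Data frame `sample_id`, `arm`, `metric`, `value`, `ci_low`,
#'   `ci_high`; rarefaction depth in attribute `rarefy_to`.
#' @export
diversity <- function(tab, rarefy_to = NULL, n_boot = 200, seed = 1) {
  stopifnot(inherits(tab, "clonotype_table"))
  ids <- tab$samples$sample_id
  if (!is.null(rarefy_to)) {
    depth <- vapply(ids, function(s) sum(sample_counts(tab, s)), 0)
    low <- ids[depth < rarefy_to]
    if (length(low))
      stop("sample(s) below rarefaction depth ", rarefy_to, ": ",
           paste(low, collapse = ", "))
  }
  set.seed(seed)
  out <- list()
  for (s in ids) {
    counts <- sample_counts(tab, s)
    arm <- tab$samples$arm[tab$samples$sample_id == s][1]
    if (is.null(rarefy_to)) {
      obs <- diversity_metrics(counts)
      depth_s <- sum(counts)
      p <- counts / depth_s
      boot <- vapply(seq_len(n_boot), function(b)
        diversity_metrics(stats::rmultinom(1, depth_s, p)[, 1]),
        numeric(4))
    } else {
      boot <- vapply(seq_len(n_boot), function(b)
        diversity_metrics(rarefy_counts(counts, rarefy_to)),
        numeric(4))
      obs <- rowMeans(boot)
    }
    ci <- apply(boot, 1, stats::quantile, probs = c(0.025, 0.975),
                na.rm = TRUE, names = FALSE)
    out[[s]] <- data.frame(sample_id = s, arm = arm,
                           metric = names(obs), value = unname(obs),
                           ci_low = ci[1, ], ci_high = ci[2, ],
                           row.names = NULL, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, c(out, make.row.names = FALSE))
  attr(out, "rarefy_to") <- rarefy_to
  out
}

#' Compare clonotype diversity between two arms
#'
#' Estimates the difference of arm means of the chosen metric, with a
#' percentile bootstrap CI from multinomial resampling of clones within
#' each sample. The arms are flagged "similar" when the whole CI lies
#' inside the user-set equivalence margin, which has no default: similarity
#' is a claim the caller must quantify.
#'
#' @param tab A [clonotype_table()] with samples from both arms.
#' @param arm_a,arm_b Arm labels compared (difference is `arm_a - arm_b`).
#' @param metric One of `"shannon"`, `"invsimpson"`, `"richness"`,
#'   `"pielou"`.
#' @param margin Equivalence margin (same units as the metric), required.
#' @param n_boot Bootstrap replicates.
#' @param seed Integer seed.
#' @return A `diversity_comparison` list: `difference`, `ci_low`,
#'   `ci_high`, `similar`, `excludes_zero`, `metric`, `margin`,
#'   `degenerate` (CI collapsed to a point).
#' @export
compare_diversity <- function(tab, arm_a, arm_b, metric = "shannon",
                              margin, n_boot = 1000, seed = 1) {
  stopifnot(inherits(tab, "clonotype_table"))
  metric <- match.arg(metric,
                      c("shannon", "invsimpson", "richness", "pielou"))
  if (missing(margin)) stop("an equivalence margin must be supplied")
  ids_a <- tab$samples$sample_id[tab$samples$arm == arm_a]
  ids_b <- tab$samples$sample_id[tab$samples$arm == arm_b]
  if (!length(ids_a) || !length(ids_b))
    stop("need at least one sample per arm")
  counts <- lapply(stats::setNames(c(ids_a, ids_b), c(ids_a, ids_b)),
                   function(s) sample_counts(tab, s))
  one <- function(cv) diversity_metrics(cv)[[metric]]
  arm_mean <- function(ids, draw) mean(vapply(ids, draw, 0))
  obs <- arm_mean(ids_a, function(s) one(counts[[s]])) -
    arm_mean(ids_b, function(s) one(counts[[s]]))
  set.seed(seed)
  boot <- numeric(n_boot)
  for (b in seq_len(n_boot)) {
    draw <- function(s) {
      cv <- counts[[s]]
      one(stats::rmultinom(1, sum(cv), cv / sum(cv))[, 1])
    }
    boot[b] <- arm_mean(ids_a, draw) - arm_mean(ids_b, draw)
  }
  ci <- stats::quantile(boot, c(0.025, 0.975), names = FALSE)
  degenerate <- ci[1] == ci[2]
  structure(list(difference = obs, ci_low = ci[1], ci_high = ci[2],
                 similar = ci[1] >= -margin && ci[2] <= margin,
                 excludes_zero = ci[1] > 0 || ci[2] < 0,
                 metric = metric, margin = margin, n_boot = n_boot,
                 seed = seed, degenerate = degenerate),
            class = "diversity_comparison")
}

#' @export
print.diversity_comparison <- function(x, ...) {
  cat(sprintf("diversity_comparison (%s): diff %.4f, 95%% CI [%.4f, %.4f]\n",
              x$metric, x$difference, x$ci_low, x$ci_high))
  cat(sprintf("equivalence margin %.4f -> %s\n", x$margin,
              if (x$similar) "similar" else "not shown similar"))
  invisible(x)
}

#' Simulate power-law clonotype tables with matched or differing diversity
#'
#' Clone probabilities are proportional to `rank^(-power_alpha)`; counts are
#' multinomial at the stated depth per arm. The true Shannon entropy and
#' inverse Simpson of each arm's probability vector are returned. `n_clones`
#' and `power_alpha` are recycled over arms, so a clonal-outgrowth
#' alternative is one call away (e.g. `n_clones = c(1000, 10)`).
#'
#' @param n_clones Clones per arm (`>= 1`).
#' @param power_alpha Power-law exponent(s) (`>= 0`).
#' @param depth Total reads per arm (`>= n_clones` is not required, but
#'   `>= 1`).
#' @param arms Arm labels (one simulated sample per arm).
#' @param seed Integer seed.
#' @return List with `tab` (a [clonotype_table()]) and `truth` (data frame
#'   `arm`, `shannon_true`, `invsimpson_true`).
#' @export
simulate_clonotypes <- function(n_clones = 1000, power_alpha = 1,
                                depth = 50000,
                                arms = c("ALWAYS_ON", "RESTED_D7_11"),
                                seed = 1) {
  if (depth < 1) stop("depth must be >= 1")
  if (any(n_clones < 1)) stop("n_clones must be >= 1")
  n_clones <- rep_len(n_clones, length(arms))
  power_alpha <- rep_len(power_alpha, length(arms))
  set.seed(seed)
  records <- list(); truth <- list()
  for (i in seq_along(arms)) {
    p <- seq_len(n_clones[i])^(-power_alpha[i])
    p <- p / sum(p)
    cnt <- stats::rmultinom(1, depth, p)[, 1]
    sid <- arms[i]
    records[[i]] <- data.frame(
      clone_id = sprintf("clone%05d", seq_len(n_clones[i])),
      sample_id = sid, count = cnt, stringsAsFactors = FALSE)
    truth[[i]] <- data.frame(arm = arms[i],
                             shannon_true = -sum(p * log(p)),
                             invsimpson_true = 1 / sum(p^2),
                             stringsAsFactors = FALSE)
  }
  tab <- clonotype_table(do.call(rbind, records),
                         data.frame(sample_id = arms, arm = arms,
                                    stringsAsFactors = FALSE))
  list(tab = tab, truth = do.call(rbind, truth))
}
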