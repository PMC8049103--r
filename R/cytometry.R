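# Preprocessing and marker-panel scoring: arcsinh transform, gating,
# stratified subsampling, pooled percentile normalization and the
# exhaustion / memory scores (normalized mean expression over the panel).

#' Arcsinh-transform an event table
#'
#' Replaces every intensity x by `asinh(x / cofactor)`, the standard
#' variance-stabilizing transform for mass-cytometry ion counts.
#'
#' @param x An untransformed `event_table`.
#' @param cofactor Positive cofactor; 5 is the mass-cytometry convention.
#' @return The transformed `event_table` with the cofactor recorded.
#' @export
arcsinh_transform <- function(x, cofactor = 5) {
  stopifnot(inherits(x, "event_table"))
  if (x$transformed)
    stop("event table is already arcsinh-transformed (cofactor ",
         x$cofactor, ")")
  if (!is.numeric(cofactor) || cofactor <= 0) stop("cofactor must be > 0")
  x$data[x$channels] <- asinh(as.matrix(x$data[x$channels]) / cofactor)
  x$transformed <- TRUE
  x$cofactor <- cofactor
  x
}

#' Build a gate-rule table
#'
#' @param channel Channel names.
#' @param comparator One of `">"`, `">="`, `"<"`, `"<="` per rule.
#' @param threshold Thresholds on the transformed scale.
#' @return Data frame of gating rules.
#' @export
gate_rules <- function(channel, comparator, threshold) {
  ok <- comparator %in% c(">", ">=", "<", "<=")
  if (!all(ok)) stop("unknown comparator: ", comparator[!ok][1])
  data.frame(channel = channel, comparator = comparator,
             threshold = threshold, stringsAsFactors = FALSE)
}

#' Default CAR+/CD8+ gate on the arcsinh scale
#' @param threshold Positivity threshold shared by both channels.
#' @return Data frame of gating rules.
#' @export
default_gate_rules <- function(threshold = 1.5) {
  gate_rules(c("CAR", "CD8"), c(">", ">"), c(threshold, threshold))
}

#' Gate events by explicit threshold rules
#'
#' Keeps cells satisfying all rules (logical AND), preserving the original
#' ordering. The number of removed cells is reported via `message()` and
#' stored in attribute `n_removed`; an empty result is returned with a
#' warning (attribute `empty_gate`), not an error.
#'
#' @param x A transformed `event_table`.
#' @param rules Data frame from [gate_rules()].
#' @return The gated `event_table`.
#' @export
gate_events <- function(x, rules) {
  stopifnot(inherits(x, "event_table"))
  if (!x$transformed) stop("gate_events requires a transformed table")
  absent <- setdiff(rules$channel, x$channels)
  if (length(absent))
    stop("gate rule on absent channel(s): ", paste(absent, collapse = ", "))
  keep <- rep(TRUE, nrow(x$data))
  for (i in seq_len(nrow(rules))) {
    v <- x$data[[rules$channel[i]]]
    keep <- keep & switch(rules$comparator[i],
                          ">"  = v >  rules$threshold[i],
                          ">=" = v >= rules$threshold[i],
                          "<"  = v <  rules$threshold[i],
                          "<=" = v <= rules$threshold[i])
  }
  n_removed <- sum(!keep)
  message(sprintf("gate removed %d of %d cells", n_removed, length(keep)))
  out <- x
  out$data <- x$data[keep, , drop = FALSE]
  rownames(out$data) <- NULL
  attr(out, "n_removed") <- n_removed
  if (nrow(out$data) == 0) {
    warning("gate removed all cells; returning empty table")
    attr(out, "empty_gate") <- TRUE
  }
  out
}

#' Subsample an event table with proportional stratification
#'
#' Draws `n_total` cells without replacement, allocated across strata
#' (default `(arm, day)`) proportionally to stratum size with
#' largest-remainder rounding; deterministic under a fixed seed. Original
#' row order of the selected cells is preserved.
#'
#' @param x An `event_table`.
#' @param n_total Number of cells to keep (`>= 1`, `<=` available cells).
#' @param stratify_by Metadata columns defining strata.
#' @param seed Integer seed.
#' @return The subsampled `event_table`.
#' @export
subsample <- function(x, n_total, stratify_by = c("arm", "day"), seed = 1) {
  stopifnot(inherits(x, "event_table"))
  n <- nrow(x$data)
  if (n_total < 1) stop("n_total must be >= 1")
  if (n_total > n)
    stop("n_total (", n_total, ") exceeds available cells (", n,
         "); lower n_total")
  strat <- interaction(x$data[stratify_by], drop = TRUE, lex.order = TRUE)
  sizes <- as.vector(table(strat))
  alloc <- largest_remainder(n_total, sizes)
  set.seed(seed)
  keep <- logical(n)
  levs <- levels(strat)
  for (i in seq_along(levs)) {
    idx <- which(strat == levs[i])
    if (alloc[i] > 0)
      keep[idx[sample.int(length(idx), alloc[i])]] <- TRUE
  }
  out <- x
  out$data <- x$data[keep, , drop = FALSE]
  rownames(out$data) <- NULL
  out
}

# Largest-remainder apportionment of n_total over strata of given sizes.
largest_remainder <- function(n_total, sizes) {
  quota <- n_total * sizes / sum(sizes)
  alloc <- floor(quota)
  rem <- n_total - sum(alloc)
  if (rem > 0) {
    frac <- quota - alloc
    frac[alloc >= sizes] <- -Inf          # cannot take more than available
    ord <- order(frac, seq_along(frac), decreasing = c(TRUE, FALSE),
                 method = "radix")
    alloc[ord[seq_len(rem)]] <- alloc[ord[seq_len(rem)]] + 1L
  }
  # safety: redistribute any overshoot (only possible with pathological input)
  while (any(over <- alloc > sizes)) {
    excess <- sum(alloc[over] - sizes[over])
    alloc[over] <- sizes[over]
    room <- which(alloc < sizes)
    for (i in room) {
      if (excess == 0) break
      add <- min(excess, sizes[i] - alloc[i])
      alloc[i] <- alloc[i] + add
      excess <- excess - add
    }
    if (excess > 0) stop("cannot allocate n_total over strata")
  }
  as.integer(alloc)
}

#' Percentile min-max normalization of markers
#'
#' For each marker, the (`p_low`, `p_high`) percentiles are computed once on
#' the pooled cells of all arms and days jointly (quantile type 7, linear
#' interpolation); values are mapped to `(x - low) / (high - low)` and
#' clipped to `[0, 1]`. Pooling makes scores comparable between conditions.
#' A degenerate marker (`high == low`) maps to 0.5 for all cells with a
#' warning naming it.
#'
#' @param x A transformed `event_table`.
#' @param p_low,p_high Percentiles in `[0, 100]`, `p_low < p_high`.
#' @param markers Channels to normalize (default: all).
#' @return A `scored_events` object (scores unset until
#'   [compute_scores()]).
#' @export
normalize_markers <- function(x, p_low = 1, p_high = 99, markers = NULL) {
  stopifnot(inherits(x, "event_table"))
  if (!x$transformed) stop("normalize_markers requires a transformed table")
  if (!(p_low >= 0 && p_low < p_high && p_high <= 100))
    stop("require 0 <= p_low < p_high <= 100")
  if (is.null(markers)) markers <- x$channels
  mat <- channel_matrix(x, markers)
  lo <- apply(mat, 2, stats::quantile, probs = p_low / 100, type = 7,
              names = FALSE)
  hi <- apply(mat, 2, stats::quantile, probs = p_high / 100, type = 7,
              names = FALSE)
  norm <- mat
  for (j in seq_along(markers)) {
    if (hi[j] == lo[j]) {
      warning("degenerate channel '", markers[j],
              "' (equal percentiles); mapped to 0.5")
      norm[, j] <- 0.5
    } else {
      norm[, j] <- pmin(1, pmax(0, (mat[, j] - lo[j]) / (hi[j] - lo[j])))
    }
  }
  structure(list(meta = x$data[c("cell_id", "sample", "arm", "day")],
                 normalized = norm,
                 bounds = data.frame(marker = markers, low = lo, high = hi,
                                     row.names = NULL),
                 p_low = p_low, p_high = p_high, quantile_type = 7L,
                 cofactor = x$cofactor,
                 exhaustion_score = NULL, memory_score = NULL,
                 panel = NULL),
            class = "scored_events")
}

#' @export
print.scored_events <- function(x, ...) {
  cat(sprintf("scored_events: %d cells x %d normalized markers\n",
              nrow(x$normalized), ncol(x$normalized)))
  if (!is.null(x$exhaustion_score))
    cat(sprintf("scores set (exhaustion mean %.3f, memory mean %.3f)\n",
                mean(x$exhaustion_score), mean(x$memory_score)))
  invisible(x)
}

#' Define the scoring panel
#'
#' @param exhaustion_markers,memory_markers Nonempty, non-duplicated channel
#'   name vectors.
#' @param gate_rules Optional gating rules carried for provenance.
#' @return A `panel_definition` list.
#' @export
panel_definition <- function(exhaustion_markers, memory_markers,
                             gate_rules = NULL) {
  if (!length(exhaustion_markers) || !length(memory_markers))
    stop("both marker lists must be nonempty")
  if (anyDuplicated(exhaustion_markers) || anyDuplicated(memory_markers))
    stop("duplicated marker within a panel list")
  structure(list(exhaustion_markers = exhaustion_markers,
                 memory_markers = memory_markers, gate_rules = gate_rules),
            class = "panel_definition")
}

#' Default exhaustion / memory scoring panel
#'
#' Exhaustion: PD-1, TIM-3, LAG-3, CTLA-4, BTLA, 2B4, CD39. Memory: CD45RA,
#' IL-7R, CD27, CD197 (CCR7).
#' @return A `panel_definition`.
#' @export
default_panel_definition <- function() {
  panel_definition(c("PD1", "TIM3", "LAG3", "CTLA4", "BTLA", "2B4", "CD39"),
                   c("CD45RA", "IL7R", "CD27", "CD197"),
                   gate_rules = default_gate_rules())
}

#' Compute per-cell exhaustion and memory scores
#'
#' Each cell's exhaustion score is the arithmetic mean of its normalized
#' exhaustion-panel markers; the memory score is the mean over the memory
#' panel. Both lie in `[0, 1]` by construction.
#'
#' @param scored A `scored_events` from [normalize_markers()].
#' @param panel A [panel_definition()].
#' @return `scored` with `exhaustion_score` and `memory_score` filled.
#' @export
compute_scores <- function(scored, panel = default_panel_definition()) {
  stopifnot(inherits(scored, "scored_events"),
            inherits(panel, "panel_definition"))
  have <- colnames(scored$normalized)
  absent <- setdiff(c(panel$exhaustion_markers, panel$memory_markers), have)
  if (length(absent))
    stop("panel marker(s) absent from normalized matrix: ",
         paste(absent, collapse = ", "))
  scored$exhaustion_score <-
    rowMeans(scored$normalized[, panel$exhaustion_markers, drop = FALSE])
  scored$memory_score <-
    rowMeans(scored$normalized[, panel$memory_markers, drop = FALSE])
  scored$panel <- panel
  scored
}

#' Write scored events as CSV with a JSON sidecar
#'
#' The CSV holds metadata, normalized markers and both scores; the sidecar
#' records normalization bounds, percentiles, quantile rule and cofactor.
#'
#' @param scored A `scored_events` with scores computed.
#' @param path CSV output path; the sidecar is `<path>.json`.
#' @export
write_scored_events <- function(scored, path) {
  stopifnot(inherits(scored, "scored_events"))
  df <- cbind(scored$meta, as.data.frame(scored$normalized,
                                         check.names = FALSE))
  if (!is.null(scored$exhaustion_score)) {
    df$exhaustion_score <- scored$exhaustion_score
    df$memory_score <- scored$memory_score
  }
  utils::write.csv(df, path, row.names = FALSE)
  side <- list(bounds = scored$bounds, p_low = scored$p_low,
               p_high = scored$p_high, quantile_type = scored$quantile_type,
               cofactor = scored$cofactor)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
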