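# Bulk expression stage: log2-CPM normalization, exhaustion-signature
# kinetics, PCA of terminal-day samples with top-PC1-loading clustering,
# and a scalar reprogramming index along PC1.

#' Construct a bulk expression set
#'
#' @param counts Nonnegative integer matrix, genes x samples, with unique
#'   row (gene) and column (sample) names.
#' @param samples Data frame with `sample_id`, `arm`, `day` and optionally
#'   `donor`, one row per column of `counts`.
#' @return An `expr_set` list.
#' @export
expr_set <- function(counts, samples) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || anyDuplicated(rownames(counts)))
    stop("counts must have unique gene rownames")
  if (is.null(colnames(counts)) || anyDuplicated(colnames(counts)))
    stop("counts must have unique sample colnames")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be nonnegative integers")
  required <- c("sample_id", "arm", "day")
  missing <- setdiff(required, names(samples))
  if (length(missing))
    stop("sample sheet is missing column(s): ",
         paste(missing, collapse = ", "))
  if (!identical(colnames(counts), samples$sample_id))
    stop("sample sheet order must match count columns")
  structure(list(counts = counts, samples = samples), class = "expr_set")
}

#' @export
print.expr_set <- function(x, ...) {
  cat(sprintf("expr_set: %d genes x %d samples (%s)\n",
              nrow(x$counts), ncol(x$counts),
              paste(unique(x$samples$arm), collapse = ", ")))
  invisible(x)
}

#' Define up/down exhaustion signature sets
#'
#' @param up_genes Genes upregulated during exhaustion.
#' @param down_genes Genes downregulated during exhaustion. The two sets
#'   must be disjoint and nonempty.
#' @return A `signature_set` list.
#' @export
signature_set <- function(up_genes, down_genes) {
  if (!length(up_genes) || !length(down_genes))
    stop("both signature sets must be nonempty")
  overlap <- intersect(up_genes, down_genes)
  if (length(overlap))
    stop("up and down sets overlap: ", paste(overlap, collapse = ", "))
  structure(list(up_genes = unique(up_genes),
                 down_genes = unique(down_genes)),
            class = "signature_set")
}

#' Demo signature: canonical exhaustion- and memory-associated genes
#'
#' Up: PDCD1, ENTPD1, BATF, NR4A1. Down: IL7R, LEF1, KLF2, BACH2. The full
#' signature used for kinetics is study-specific and supplied by the caller;
#' this small named set ships for demonstrations.
#' @return A `signature_set`.
#' @export
demo_signatures <- function() {
  signature_set(c("PDCD1", "ENTPD1", "BATF", "NR4A1"),
                c("IL7R", "LEF1", "KLF2", "BACH2"))
}

#' Default synthetic signature: 50 up and 50 down genes
#'
#' The first members are the canonical named genes of [demo_signatures()];
#' the remainder are synthetic identifiers matched to the bulk generator.
#' @param n_up,n_down Set sizes.
#' @return A `signature_set`.
#' @export
default_signatures <- function(n_up = 50, n_down = 50) {
  up <- c("PDCD1", "ENTPD1", "BATF", "NR4A1",
          sprintf("EXUP%03d", seq_len(max(0, n_up - 4))))
  dn <- c("IL7R", "LEF1", "KLF2", "BACH2",
          sprintf("EXDN%03d", seq_len(max(0, n_down - 4))))
  signature_set(up[seq_len(n_up)], dn[seq_len(n_down)])
}

#' Normalize counts to log2 counts-per-million
#'
#' `value = log2((count / library_size) * 1e6 + pseudocount)` with
#' `library_size` the per-sample column sum.
#'
#' @param es An `expr_set`.
#' @param pseudocount Added inside the log (default 1).
#' @return Numeric matrix of log2-CPM values with the input dimnames.
#' @export
normalize_counts <- function(es, pseudocount = 1) {
  stopifnot(inherits(es, "expr_set"))
  lib <- colSums(es$counts)
  if (any(lib == 0))
    stop("zero library size in sample(s): ",
         paste(colnames(es$counts)[lib == 0], collapse = ", "))
  out <- log2(sweep(es$counts, 2, lib, "/") * 1e6 + pseudocount)
  attr(out, "pseudocount") <- pseudocount
  out
}

#' Signature kinetics: mean z-scored expression of up/down sets over time
#'
#' Each gene is z-scored across all samples (constant genes are guarded to
#' zero with a warning); each sample's signature value is the mean over the
#' set's genes; values are then summarized per (arm, day) as mean with
#' across-replicate SEM. Signature genes absent from the matrix are dropped
#' and reported via `message()`.
#'
#' @param norm log2-CPM matrix from [normalize_counts()].
#' @param samples Sample sheet aligned with `norm` columns.
#' @param signatures A [signature_set()].
#' @return Data frame `arm`, `day`, `set` (`up`/`down`), `mean`, `sem`,
#'   `n`; per-sample values in attribute `sample_values`.
#' @export
signature_kinetics <- function(norm, samples, signatures) {
  stopifnot(inherits(signatures, "signature_set"))
  z <- gene_zscore(norm)
  per_set <- list()
  for (set in c("up", "down")) {
    genes <- if (set == "up") signatures$up_genes else signatures$down_genes
    present <- intersect(genes, rownames(norm))
    dropped <- setdiff(genes, present)
    if (length(dropped))
      message("dropping ", length(dropped), " absent ", set,
              "-signature gene(s): ",
              paste(utils::head(dropped, 5), collapse = ", "),
              if (length(dropped) > 5) ", ..." else "")
    if (!length(present))
      stop("all ", set, "-signature genes absent from matrix")
    per_set[[set]] <- colMeans(z[present, , drop = FALSE])
  }
  out <- list()
  for (set in c("up", "down")) {
    v <- per_set[[set]]
    for (a in unique(samples$arm)) for (d in sort(unique(samples$day))) {
      sel <- samples$arm == a & samples$day == d
      if (!any(sel)) next
      vv <- v[sel]
      out[[length(out) + 1L]] <-
        data.frame(arm = a, day = d, set = set, mean = mean(vv),
                   sem = if (length(vv) > 1)
                           stats::sd(vv) / sqrt(length(vv)) else NA_real_,
                   n = length(vv), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, out)
  attr(out, "sample_values") <-
    data.frame(sample_id = samples$sample_id, arm = samples$arm,
               day = samples$day, up = per_set$up, down = per_set$down,
               row.names = NULL, stringsAsFactors = FALSE)
  out
}

# Per-gene z-score across samples; zero-variance genes map to 0 with a
# single warning listing how many.
gene_zscore <- function(norm) {
  mu <- rowMeans(norm)
  sd <- apply(norm, 1, stats::sd)
  flat <- sd == 0
  if (any(flat)) {
    warning(sum(flat), " constant gene(s) z-scored to 0")
    sd[flat] <- 1
  }
  (norm - mu) / sd
}

#' PCA of one day's samples with top-PC1-loading gene clustering
#'
#' Singular value decomposition of the gene-centered (optionally
#' unit-scaled) matrix restricted to the chosen day. The PC1 sign is fixed
#' so the `positive_arm` centroid has a positive PC1 score. Genes are
#' ranked by absolute PC1 loading and the top `n_top` are clustered
#' hierarchically (average linkage, 1 - Pearson correlation distance).
#'
#' @param norm log2-CPM matrix.
#' @param samples Sample sheet aligned with `norm` columns.
#' @param day Day whose samples are analyzed (default: maximum).
#' @param n_top Number of top-loading genes (truncated with a warning when
#'   it exceeds the gene count).
#' @param scale. Unit-scale genes before decomposition.
#' @param positive_arm Arm anchoring the PC1 sign convention.
#' @return List with `scores` (`sample_id`, `arm`, `day`, `PC1`, `PC2`),
#'   `var_explained`, `loadings` (ranked by |PC1 loading|), `top_genes`,
#'   `hclust` and `dendro_order`.
#' @export
pca_top_loadings <- function(norm, samples, day = NULL, n_top = 500,
                             scale. = FALSE, positive_arm = "ALWAYS_ON") {
  if (is.null(day)) day <- max(samples$day)
  sel <- which(samples$day == day)
  if (length(sel) < 3) stop("need at least 3 samples at day ", day)
  X <- t(norm[, sel, drop = FALSE])          # samples x genes
  if (scale.) {
    keep <- apply(X, 2, stats::sd) > 0
    X <- X[, keep, drop = FALSE]
  }
  pc <- stats::prcomp(X, center = TRUE, scale. = scale.)
  scores <- pc$x
  loadings <- pc$rotation
  if (positive_arm %in% samples$arm[sel]) {
    if (mean(scores[samples$arm[sel] == positive_arm, 1]) < 0) {
      scores[, 1] <- -scores[, 1]
      loadings[, 1] <- -loadings[, 1]
    }
  }
  if (n_top > nrow(loadings)) {
    warning("n_top truncated to ", nrow(loadings), " genes")
    n_top <- nrow(loadings)
  }
  ord <- order(abs(loadings[, 1]), decreasing = TRUE)
  top <- rownames(loadings)[ord[seq_len(n_top)]]
  sub <- norm[top, sel, drop = FALSE]
  cc <- suppressWarnings(stats::cor(t(sub)))
  cc[!is.finite(cc)] <- 0                    # constant genes: max distance
  hc <- stats::hclust(stats::as.dist(1 - cc), method = "average")
  list(scores = data.frame(sample_id = samples$sample_id[sel],
                           arm = samples$arm[sel], day = day,
                           PC1 = scores[, 1],
                           PC2 = if (ncol(scores) >= 2) scores[, 2] else 0,
                           row.names = NULL, stringsAsFactors = FALSE),
       var_explained = pc$sdev^2 / sum(pc$sdev^2),
       loadings = data.frame(gene = rownames(loadings)[ord],
                             loading_pc1 = loadings[ord, 1],
                             rank = seq_along(ord), row.names = NULL,
                             stringsAsFactors = FALSE),
       top_genes = top, hclust = hc, dendro_order = top[hc$order])
}

#' Reprogramming index along PC1
#'
#' `clamp01((d(R, ON) - d(R, OFF)) / d(ON, OFF))` with `d` the distance
#' between arm centroids on PC1: 1 means the rested centroid sits at the
#' ALWAYS_OFF centroid (complete transcriptomic reversal), 0 means at or
#' beyond ALWAYS_ON (no reversal).
#'
#' @param pc1 PC1 scores.
#' @param arms Arm label per score.
#' @param on,off Labels of the always-on / always-off arms.
#' @param rested Label of the rested arm (default: the remaining label).
#' @return Scalar in `[0, 1]`.
#' @export
reprogramming_index <- function(pc1, arms, on = "ALWAYS_ON",
                                off = "ALWAYS_OFF", rested = NULL) {
  if (is.null(rested)) {
    rest_labels <- setdiff(unique(arms), c(on, off))
    if (length(rest_labels) != 1)
      stop("cannot infer the rested arm; pass `rested`")
    rested <- rest_labels
  }
  for (a in c(on, off, rested))
    if (!any(arms == a)) stop("arm '", a, "' has no samples")
  c_on <- mean(pc1[arms == on]); c_off <- mean(pc1[arms == off])
  c_r <- mean(pc1[arms == rested])
  d_onoff <- abs(c_on - c_off)
  if (d_onoff == 0) stop("undefined index: ON and OFF centroids coincide")
  min(1, max(0, (abs(c_r - c_on) - abs(c_r - c_off)) / d_onoff))
}
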