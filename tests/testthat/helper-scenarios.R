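# Shared fixtures and independent oracles, built in code at test time.

# Small default-scenario simulation -> scored events + latent truth.
small_scored <- function(n = 300, seed = 1, ...) {
  sim <- simulate_cytometry(sim_config(n_cells_per_arm_day = n,
                                       seed = seed, ...))
  ev <- arcsinh_transform(sim$events, 5)
  scored <- compute_scores(normalize_markers(ev))
  list(scored = scored, truth = sim$truth, events = sim$events)
}

# Hand-built scored_events around an explicit normalized matrix.
toy_scored <- function(normalized, day = NULL, arm = NULL) {
  n <- nrow(normalized)
  if (is.null(day)) day <- rep(1L, n)
  if (is.null(arm)) arm <- rep("A", n)
  structure(list(
    meta = data.frame(cell_id = sprintf("c%03d", seq_len(n)),
                      sample = paste0(arm, "_D", day), arm = arm,
                      day = day, stringsAsFactors = FALSE),
    normalized = normalized,
    bounds = data.frame(marker = colnames(normalized), low = 0, high = 1),
    p_low = 1, p_high = 99, quantile_type = 7L, cofactor = 5,
    exhaustion_score = NULL, memory_score = NULL, panel = NULL),
    class = "scored_events")
}

# Hand-built transformed event_table around an intensity matrix.
toy_events <- function(mat, day = NULL, arm = NULL, transformed = TRUE) {
  n <- nrow(mat)
  if (is.null(colnames(mat)))
    colnames(mat) <- sprintf("M%d", seq_len(ncol(mat)))
  if (is.null(day)) day <- rep(1L, n)
  if (is.null(arm)) arm <- rep("A", n)
  df <- data.frame(cell_id = sprintf("c%03d", seq_len(n)),
                   sample = paste0(arm, "_D", day), arm = arm, day = day,
                   stringsAsFactors = FALSE)
  event_table(cbind(df, as.data.frame(mat, check.names = FALSE)),
              channels = colnames(mat), transformed = transformed,
              cofactor = if (transformed) 5 else NA_real_)
}

# Exhaustive O(n^2) k-nearest-neighbour oracle with the ascending-index
# tie rule, independent of the package's blocked implementation.
brute_knn <- function(X, k, query_idx, ref_idx, exclude_self = FALSE) {
  t(vapply(query_idx, function(i) {
    d <- sqrt(colSums((t(X[ref_idx, , drop = FALSE]) - X[i, ])^2))
    if (exclude_self) d[ref_idx == i] <- Inf
    ref_idx[order(d, seq_along(d))][seq_len(k)]
  }, integer(k)))
}

# Independent type-7 quantile: linear interpolation of order statistics.
quantile7 <- function(x, p) {
  x <- sort(x)
  h <- (length(x) - 1) * p + 1
  lo <- floor(h)
  x[lo] + (h - lo) * (x[pmin(lo + 1, length(x))] - x[lo])
}
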