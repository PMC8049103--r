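# Score kinetics: tricube-weighted local polynomial regression of per-cell
# scores on day with a case-resampling bootstrap 95% band, and a
# permutation test for a time trend in the least-squares slope.

# Local polynomial fit evaluated on a grid only. At each grid point the
# nearest ceiling(span * n) observations define the window; weights are
# tricube in |x - x0| / h with h the window radius. A window whose positive-
# weight points span too few distinct x values (possible at the boundary,
# where the farthest points carry zero tricube weight) falls back to the
# local weighted mean, which is the correct local estimate there.
local_poly_fit <- function(x, y, grid, span, degree) {
  n <- length(x)
  q <- ceiling(span * n)
  if (q < degree + 1L)
    stop("span too small to cover a polynomial window; use span >= ",
         signif((degree + 1) / n, 3))
  out <- numeric(length(grid))
  for (gi in seq_along(grid)) {
    d <- abs(x - grid[gi])
    h <- sort(d, partial = q)[q]
    if (h == 0) {                       # all window points at x0
      out[gi] <- mean(y[d == 0])
      next
    }
    w <- (1 - pmin(d / h, 1)^3)^3
    use <- w > 0
    if (length(unique(x[use])) <= degree) {
      out[gi] <- sum(w[use] * y[use]) / sum(w[use])
      next
    }
    X <- outer(x[use] - grid[gi], 0:degree, "^")
    fit <- stats::lm.wfit(X, y[use], w[use])
    out[gi] <- fit$coefficients[1]
  }
  out
}

#' Local polynomial regression of scores on day with a bootstrap band
#'
#' Fits a tricube-weighted local polynomial (degree 1 or 2) of score against
#' day, evaluated on a grid spanning the observed day range, with a 95%
#' pointwise band from the 2.5/97.5 percentiles of `n_boot` case-resampling
#' bootstrap refits. The band is clipped outward to contain the point
#' estimate so `ci_low <= fitted <= ci_high` holds pointwise. Constant
#' scores give a flat fit with a zero-width band and a warning.
#'
#' @param day,score Per-cell day and score vectors (one arm, one score
#'   kind); at least 2 distinct days.
#' @param span Bandwidth fraction in `(0, 1]`.
#' @param degree Local polynomial degree, 1 or 2.
#' @param n_boot Bootstrap replicates (`>= 100`).
#' @param seed Integer seed.
#' @param grid Evaluation grid (default 40 equally spaced days).
#' @return A `kinetics_fit`: `grid`, `fitted`, `ci_low`, `ci_high` plus the
#'   parameters used.
#' @export
fit_local_regression <- function(day, score, span = 0.75, degree = 1,
                                 n_boot = 500, seed = 1, grid = NULL) {
  stopifnot(length(day) == length(score))
  if (length(unique(day)) < 2) stop("need at least 2 distinct days")
  if (!(span > 0 && span <= 1)) stop("span must be in (0, 1]")
  if (!degree %in% c(1, 2)) stop("degree must be 1 or 2")
  if (n_boot < 100) stop("n_boot must be >= 100")
  if (is.null(grid))
    grid <- seq(min(day), max(day), length.out = 40)
  if (any(diff(grid) <= 0)) stop("grid must be strictly increasing")
  n <- length(day)
  if (stats::var(score) == 0) {
    warning("all scores identical; flat fit with zero-width band")
    flat <- rep(score[1], length(grid))
    return(structure(list(grid = grid, fitted = flat, ci_low = flat,
                          ci_high = flat, span = span, degree = degree,
                          n_boot = n_boot, seed = seed, n = n),
                     class = "kinetics_fit"))
  }
  fitted <- local_poly_fit(day, score, grid, span, degree)
  set.seed(seed)
  boot <- matrix(NA_real_, n_boot, length(grid))
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    boot[b, ] <- local_poly_fit(day[idx], score[idx], grid, span, degree)
  }
  ci <- apply(boot, 2, stats::quantile, probs = c(0.025, 0.975),
              names = FALSE)
  structure(list(grid = grid, fitted = fitted,
                 ci_low = pmin(ci[1, ], fitted),
                 ci_high = pmax(ci[2, ], fitted),
                 span = span, degree = degree, n_boot = n_boot,
                 seed = seed, n = n),
            class = "kinetics_fit")
}

#' @export
print.kinetics_fit <- function(x, ...) {
  cat(sprintf("kinetics_fit: n = %d, span %.2f, degree %d, %d bootstrap replicates\n",
              x$n, x$span, x$degree, x$n_boot))
  cat(sprintf("fitted range [%.3f, %.3f] over days [%g, %g]\n",
              min(x$fitted), max(x$fitted), min(x$grid), max(x$grid)))
  invisible(x)
}

#' Permutation test for a time trend in scores
#'
#' The statistic is the least-squares slope of score on day; significance is
#' assessed by permuting day labels. The p-value is
#' `(1 + #permuted |slope| >= observed |slope|) / (n_perm + 1)`.
#'
#' @param day,score Per-cell day and score vectors; at least 2 distinct
#'   days.
#' @param n_perm Number of permutations (`>= 999`).
#' @param seed Integer seed.
#' @return A `trend_result` with `slope` (score units per day), `p_perm`,
#'   `n_perm`, `seed`.
#' @export
trend_test <- function(day, score, n_perm = 999, seed = 1) {
  stopifnot(length(day) == length(score))
  if (length(unique(day)) < 2)
    stop("trend undefined: need at least 2 distinct days")
  if (n_perm < 999) stop("n_perm must be >= 999")
  n <- length(day)
  dc <- day - mean(day)
  ssx <- sum(dc^2)
  slope <- sum(dc * score) / ssx
  set.seed(seed)
  idx <- vapply(seq_len(n_perm), function(i) sample.int(n),
                integer(n))
  perm_slopes <- as.vector(crossprod(dc, matrix(score[idx], n))) / ssx
  p <- (1 + sum(abs(perm_slopes) >= abs(slope))) / (n_perm + 1)
  structure(list(slope = slope, p_perm = p, n_perm = n_perm, seed = seed,
                 n = n),
            class = "trend_result")
}

#' @export
print.trend_result <- function(x, ...) {
  cat(sprintf("trend_result: slope %.5f per day, p = %.4g (%d permutations)\n",
              x$slope, x$p_perm, x$n_perm))
  invisible(x)
}

#' Fit score kinetics for every arm and score kind
#'
#' Convenience wrapper running [fit_local_regression()] and [trend_test()]
#' per (arm, score kind) on a `scored_events`.
#'
#' @param scored A `scored_events` with scores computed.
#' @param span,degree,n_boot,n_perm,seed Passed to the underlying fits; the
#'   seed is offset per arm/kind so streams do not collide.
#' @return List with `fits` (named list of `kinetics_fit`) and `trends`
#'   (data frame `arm`, `score_kind`, `slope`, `p_perm`).
#' @export
score_kinetics <- function(scored, span = 0.75, degree = 1, n_boot = 500,
                           n_perm = 999, seed = 1) {
  stopifnot(inherits(scored, "scored_events"))
  if (is.null(scored$exhaustion_score))
    stop("compute_scores must be run first")
  arms <- unique(scored$meta$arm)
  fits <- list(); rows <- list()
  off <- 0L
  for (a in arms) {
    sel <- scored$meta$arm == a
    for (kind in c("exhaustion", "memory")) {
      sc <- if (kind == "exhaustion") scored$exhaustion_score[sel]
            else scored$memory_score[sel]
      key <- paste(a, kind, sep = ".")
      fits[[key]] <- fit_local_regression(scored$meta$day[sel], sc,
                                          span = span, degree = degree,
                                          n_boot = n_boot,
                                          seed = seed + off)
      tr <- trend_test(scored$meta$day[sel], sc, n_perm = n_perm,
                       seed = seed + off)
      rows[[key]] <- data.frame(arm = a, score_kind = kind,
                                slope = tr$slope, p_perm = tr$p_perm,
                                stringsAsFactors = FALSE)
      off <- off + 1L
    }
  }
  list(fits = fits, trends = do.call(rbind, c(rows, make.row.names = FALSE)))
}
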