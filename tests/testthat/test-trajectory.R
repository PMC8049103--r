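# Temporal kNN graph, force-directed layout, region detection and
# quantification.

test_that("kNN edges on a 3-point line match the hand-derived set", {
  sc <- toy_scored(matrix(c(0, 1, 3), 3, 1, dimnames = list(NULL, "M")))
  g <- build_temporal_knn(sc, feature_markers = "M", k_within = 1,
                          k_between = 0)
  edges <- g$edges[order(g$edges$from, g$edges$to), ]
  expect_identical(edges$from, c(1L, 2L))
  expect_identical(edges$to, c(2L, 3L))
  expect_true(all(edges$type == "WITHIN_DAY"))
})

test_that("a single-day table yields no cross-day edges", {
  sc <- toy_scored(matrix(stats::runif(20), 10, 2,
                          dimnames = list(NULL, c("A", "B"))))
  g <- build_temporal_knn(sc, feature_markers = c("A", "B"),
                          k_within = 3, k_between = 5)
  expect_identical(sum(g$edges$type == "CROSS_DAY"), 0L)
})

test_that("graph equals an exhaustive O(n^2) scan on a 50-cell instance", {
  set.seed(8)
  X <- matrix(stats::runif(150), 50, 3,
              dimnames = list(NULL, c("A", "B", "C")))
  day <- rep(c(1L, 2L), c(30, 20))
  sc <- toy_scored(X, day = day)
  k_w <- 3; k_b <- 2
  g <- build_temporal_knn(sc, feature_markers = c("A", "B", "C"),
                          k_within = k_w, k_between = k_b)
  # oracle: brute-force pairwise distances with the same tie rule
  pairs <- character()
  for (d in 1:2) {
    idx <- which(day == d)
    nn <- brute_knn(X, k_w, idx, idx, exclude_self = TRUE)
    pairs <- c(pairs, paste(pmin(rep(idx, k_w), as.vector(nn)),
                            pmax(rep(idx, k_w), as.vector(nn))))
  }
  i1 <- which(day == 1); i2 <- which(day == 2)
  nn12 <- brute_knn(X, k_b, i1, i2)
  nn21 <- brute_knn(X, k_b, i2, i1)
  pairs <- c(pairs,
             paste(pmin(rep(i1, k_b), as.vector(nn12)),
                   pmax(rep(i1, k_b), as.vector(nn12))),
             paste(pmin(rep(i2, k_b), as.vector(nn21)),
                   pmax(rep(i2, k_b), as.vector(nn21))))
  expect_setequal(paste(g$edges$from, g$edges$to), unique(pairs))
})

test_that("k is truncated with a warning on small strata", {
  sc <- toy_scored(matrix(stats::runif(8), 4, 2,
                          dimnames = list(NULL, c("A", "B"))))
  expect_warning(g <- build_temporal_knn(sc, c("A", "B"), k_within = 10,
                                         k_between = 0), "truncated")
  expect_equal(nrow(g$edges), choose(4, 2))  # complete graph
  expect_error(build_temporal_knn(sc, c("A", "B"), k_within = 1,
                                  metric = "mahalanobis"), "unknown metric")
})

test_that("layout is seed-deterministic and separates components", {
  edges <- rbind(
    expand.grid(from = 1:10, to = 1:10),
    expand.grid(from = 11:20, to = 11:20))
  edges <- edges[edges$from < edges$to, ]
  edges$type <- "WITHIN_DAY"
  g <- structure(list(
    nodes = data.frame(cell_id = sprintf("c%02d", 1:20), sample = "s",
                       arm = "A", day = 1),
    edges = edges, k_within = 9, k_between = 0, metric = "euclidean",
    feature_markers = "M", layout = NULL), class = "trajectory_graph")
  expect_message(l1 <- layout_graph(g, iterations = 100, seed = 4),
                 "components")
  l2 <- suppressMessages(layout_graph(g, iterations = 100, seed = 4))
  expect_identical(l1$layout, l2$layout)
  xy <- as.matrix(l1$layout[, c("x", "y")])
  expect_equal(unname(colMeans(xy)), c(0, 0), tolerance = 1e-9)
  cent1 <- colMeans(xy[1:10, ]); cent2 <- colMeans(xy[11:20, ])
  between <- sqrt(sum((cent1 - cent2)^2))
  within <- function(rows) mean(dist(xy[rows, ]))
  expect_gt(between, within(1:10))
  expect_gt(between, within(11:20))
})

test_that("regions recover two separated clouds exactly", {
  set.seed(9)
  X <- rbind(matrix(stats::rnorm(60, 0, 0.02), 30, 2),
             matrix(stats::rnorm(40, 1, 0.02), 20, 2))
  colnames(X) <- c("A", "B")
  sc <- toy_scored(X)
  sc$exhaustion_score <- rowMeans(X)
  sc$memory_score <- 1 - rowMeans(X)
  reg <- detect_regions(sc, terminal_day = 1, R = 2, seed = 5,
                        feature_markers = c("A", "B"))
  truth <- rep(c(2L, 1L), c(30, 20))   # cloud at 1 is the more exhausted
  expect_identical(reg$region, truth)
  expect_error(detect_regions(sc, terminal_day = 1, R = 51, seed = 1,
                              feature_markers = c("A", "B")), "distinct")
})

test_that("region membership is invariant to cell order", {
  sim <- small_scored(n = 120, seed = 6)
  reg <- detect_regions(sim$scored, R = 4, seed = 2)
  perm_sc <- sim$scored
  set.seed(3)
  ord <- sample.int(nrow(perm_sc$meta))
  perm_sc$meta <- perm_sc$meta[ord, ]
  perm_sc$normalized <- perm_sc$normalized[ord, , drop = FALSE]
  perm_sc$exhaustion_score <- perm_sc$exhaustion_score[ord]
  perm_sc$memory_score <- perm_sc$memory_score[ord]
  reg_p <- detect_regions(perm_sc, R = 4, seed = 2)
  m <- match(reg$cell_id, reg_p$cell_id)
  expect_identical(reg$region, reg_p$region[m])
})

test_that("composition percentages are exact and conserve to 100", {
  asg <- structure(list(
    cell_id = sprintf("c%03d", 1:100),
    arm = rep("A", 100),
    region = rep(1:4, c(10, 30, 40, 20)), R = 4L, terminal_day = 11),
    class = "region_assignment")
  comp <- region_composition(asg)
  expect_equal(comp$pct, c(10, 30, 40, 20))
  # toy 12-cell table vs hand tally
  asg2 <- structure(list(
    cell_id = sprintf("c%03d", 1:12),
    arm = c("ON", "ON", "R", "ON", "R", "R", "ON", "R", "ON", "R", "R", "ON"),
    region = c(1L, 1L, 3L, 2L, 4L, 3L, 1L, 4L, 2L, 3L, 4L, 4L),
    R = 4L, terminal_day = 11), class = "region_assignment")
  comp2 <- region_composition(asg2)
  # hand tally: ON = {1:3, 2:2, 3:0, 4:1} of 6; R = {3:3, 4:3} of 6
  expect_equal(comp2$pct[comp2$arm == "ON"], c(3, 2, 0, 1) / 6 * 100)
  expect_equal(comp2$pct[comp2$arm == "R"], c(0, 0, 3, 3) / 6 * 100)
  for (a in unique(comp2$arm))
    expect_equal(sum(comp2$pct[comp2$arm == a]), 100, tolerance = 1e-9)
  # random inputs conserve too
  set.seed(4)
  asg3 <- asg
  asg3$region <- sample.int(4, 100, replace = TRUE)
  asg3$arm <- sample(c("X", "Y"), 100, replace = TRUE)
  comp3 <- region_composition(asg3)
  for (a in c("X", "Y"))
    expect_equal(sum(comp3$pct[comp3$arm == a]), 100, tolerance = 1e-9)
})

test_that("region score summaries match order-statistics oracles", {
  sc <- toy_scored(matrix(0.5, 11, 1, dimnames = list(NULL, "M")))
  sc$exhaustion_score <- c(0.1, 0.2, 0.3, 0.4,
                           0.62, 0.55, 0.71, 0.48, 0.66, 0.59, 0.9)
  sc$memory_score <- 1 - sc$exhaustion_score
  asg <- structure(list(cell_id = sc$meta$cell_id,
                        arm = sc$meta$arm,
                        region = rep(c(1L, 2L, 3L), c(4, 6, 1)),
                        R = 3L, terminal_day = 1),
                   class = "region_assignment")
  s <- region_score_summary(sc, asg)
  r1 <- s[s$region == 1 & s$score_kind == "exhaustion", ]
  expect_equal(r1$median, 0.25)
  expect_equal(r1$mean, 0.25)
  seven <- sc$exhaustion_score[5:10]
  r2 <- s[s$region == 2 & s$score_kind == "exhaustion", ]
  expect_equal(r2$q1, quantile7(seven, 0.25), tolerance = 1e-12)
  expect_equal(r2$median, quantile7(seven, 0.5), tolerance = 1e-12)
  expect_equal(r2$q3, quantile7(seven, 0.75), tolerance = 1e-12)
  r3 <- s[s$region == 3 & s$score_kind == "exhaustion", ]
  expect_true(all(c(r3$q1, r3$median, r3$q3, r3$mean) == 0.9))
  expect_identical(attr(s, "quantile_type"), 7L)
})
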