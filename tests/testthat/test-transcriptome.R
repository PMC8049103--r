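# Bulk expression stage: normalization, signature kinetics, PCA loadings
# and the reprogramming index.

toy_es <- function(counts) {
  colnames(counts) <- sprintf("s%d", seq_len(ncol(counts)))
  rownames(counts) <- sprintf("g%d", seq_len(nrow(counts)))
  expr_set(counts, data.frame(sample_id = colnames(counts),
                              arm = "A", day = 15,
                              stringsAsFactors = FALSE))
}

test_that("log2-CPM normalization matches closed forms", {
  es <- toy_es(matrix(c(1e6, 0), 2, 1))
  norm0 <- normalize_counts(es, pseudocount = 0)
  expect_equal(norm0[1, 1], log2(1e6), tolerance = 1e-12)
  expect_equal(log2(1e6), 19.93, tolerance = 1e-3)
  norm1 <- normalize_counts(es, pseudocount = 1)
  expect_equal(norm1[2, 1], 0)
  # doubling a sample's counts leaves CPM unchanged at pseudocount 0
  m <- matrix(c(10, 30, 60, 20, 60, 120), 3, 2)
  es2 <- toy_es(m)
  n2 <- normalize_counts(es2, pseudocount = 0)
  expect_equal(n2[, 1], n2[, 2], tolerance = 1e-12)
  expect_error(normalize_counts(toy_es(matrix(c(1, 1, 0, 0), 2, 2))), "s2")
})

test_that("expr_set validates counts and metadata", {
  m <- matrix(1:4, 2, 2, dimnames = list(c("a", "b"), c("s1", "s2")))
  meta <- data.frame(sample_id = c("s1", "s2"), arm = "A", day = 1)
  expect_silent(expr_set(m, meta))
  m2 <- m; m2[1] <- -1
  expect_error(expr_set(m2, meta), "nonnegative")
  m3 <- m; m3[1] <- 1.5
  expect_error(expr_set(m3, meta), "integer")
  expect_error(expr_set(m, meta[, 1:2]), "day")
})

test_that("signature kinetics matches hand-computed z-score means", {
  counts <- matrix(c(10, 100, 50,
                     20, 200, 50,
                     40, 400, 50), 3, 3,
                   dimnames = list(c("u1", "u2", "bg"),
                                   c("s1", "s2", "s3")))
  samples <- data.frame(sample_id = c("s1", "s2", "s3"),
                        arm = c("A", "A", "B"), day = c(1, 2, 2),
                        stringsAsFactors = FALSE)
  es <- expr_set(counts, samples)
  norm <- normalize_counts(es, pseudocount = 0)
  sig <- signature_set("u1", c("u2"))
  out <- signature_kinetics(norm, samples, sig)
  # oracle: z-score of u1 across the three samples, by explicit arithmetic
  v <- norm["u1", ]
  z <- (v - mean(v)) / stats::sd(v)
  expect_equal(out$mean[out$set == "up" & out$arm == "A" & out$day == 1],
               unname(z[1]), tolerance = 1e-12)
  expect_equal(out$mean[out$set == "up" & out$arm == "B"],
               unname(z[3]), tolerance = 1e-12)
})

test_that("constant signature genes are guarded to zero with a warning", {
  counts <- matrix(c(50, 10, 50, 20, 50, 40), 2, 3,
                   dimnames = list(c("flat", "var"), c("s1", "s2", "s3")))
  samples <- data.frame(sample_id = c("s1", "s2", "s3"), arm = "A",
                        day = 1:3, stringsAsFactors = FALSE)
  norm <- counts  # use raw values as the normalized matrix directly
  expect_warning(out <- signature_kinetics(norm, samples,
                                           signature_set("flat", "var")),
                 "constant")
  expect_true(all(out$mean[out$set == "up"] == 0))
  expect_error(
    suppressWarnings(signature_kinetics(norm, samples,
                                        signature_set("absent", "var"))),
    "absent")
})

test_that("signature kinetics are invariant to gene and sample order", {
  sim <- simulate_bulk_counts(n_genes = 300, seed = 31)
  norm <- normalize_counts(sim$es)
  sig <- default_signatures()
  a <- signature_kinetics(norm, sim$es$samples, sig)
  ord_g <- sample(nrow(norm)); ord_s <- sample(ncol(norm))
  b <- signature_kinetics(norm[ord_g, ord_s],
                          sim$es$samples[ord_s, ], sig)
  b <- b[order(match(paste(b$arm, b$day, b$set),
                     paste(a$arm, a$day, a$set))), ]
  expect_equal(a$mean, b$mean, tolerance = 1e-12)
  expect_equal(a$sem, b$sem, tolerance = 1e-12)
})

test_that("PC1 loadings recover the gene vector of a rank-1 matrix", {
  set.seed(13)
  gene_vec <- stats::rnorm(100)
  sample_vec <- stats::rnorm(8)
  norm <- outer(gene_vec, sample_vec)
  dimnames(norm) <- list(sprintf("g%d", 1:100), sprintf("s%d", 1:8))
  samples <- data.frame(sample_id = colnames(norm),
                        arm = rep(c("ALWAYS_ON", "ALWAYS_OFF"), 4),
                        day = 15, stringsAsFactors = FALSE)
  pc <- pca_top_loadings(norm, samples, day = 15, n_top = 20)
  lo <- pc$loadings
  v <- lo$loading_pc1[order(match(lo$gene, rownames(norm)))]
  cosine <- abs(sum(v * gene_vec)) / sqrt(sum(v^2) * sum(gene_vec^2))
  expect_gt(cosine, 0.999)
  expect_identical(length(pc$top_genes), 20L)
  expect_identical(sort(pc$hclust$order), 1:20)
})

test_that("PC scores ignore per-gene constants and fix the sign convention", {
  sim <- simulate_bulk_counts(n_genes = 300, seed = 17)
  norm <- normalize_counts(sim$es)
  samples <- sim$es$samples
  p1 <- pca_top_loadings(norm, samples, n_top = 50)
  shifted <- norm
  shifted[5, ] <- shifted[5, ] + 100
  p2 <- pca_top_loadings(shifted, samples, n_top = 50)
  expect_equal(p1$scores$PC1, p2$scores$PC1, tolerance = 1e-8)
  on_mean <- mean(p1$scores$PC1[p1$scores$arm == "ALWAYS_ON"])
  expect_gt(on_mean, 0)
  expect_warning(pca_top_loadings(norm, samples, n_top = 1e5), "truncated")
})

test_that("reprogramming index evaluates its closed-form cases", {
  arms <- c("ALWAYS_ON", "ALWAYS_OFF", "RESTED")
  expect_equal(reprogramming_index(c(4, 0, 0), arms), 1)
  expect_equal(reprogramming_index(c(4, 0, 4), arms), 0)
  expect_equal(reprogramming_index(c(4, 0, 1), arms), 0.5)
  expect_error(reprogramming_index(c(1, 1, 1), arms), "coincide")
  expect_error(reprogramming_index(c(1, 0, 0.5),
                                   c("ALWAYS_ON", "ALWAYS_OFF", "R"),
                                   rested = "ZZ"), "ZZ")
})

test_that("the reprogramming index has no preferred direction under the null", {
  idx <- numeric(200)
  for (r in seq_len(200)) {
    sim <- simulate_bulk_counts(n_genes = 400, effect_size = 0,
                                seed = 90000 + r)
    pc <- pca_top_loadings(normalize_counts(sim$es), sim$es$samples,
                           day = 15, n_top = 100)
    idx[r] <- reprogramming_index(pc$scores$PC1, pc$scores$arm)
  }
  # clamped symmetric geometry: mean stays near 1/2
  expect_gte(mean(idx), 0.4)
  expect_lte(mean(idx), 0.6)
})

test_that("up-signature rises with tonic signaling and reverses on rest", {
  hits <- 0L
  n_rep <- 100
  for (r in seq_len(n_rep)) {
    sim <- simulate_bulk_counts(n_genes = 300, seed = 5000 + r)
    norm <- normalize_counts(sim$es)
    sig <- signature_kinetics(norm, sim$es$samples, default_signatures())
    up_on <- sig$mean[sig$set == "up" & sig$arm == "ALWAYS_ON"]
    up_rest <- sig$mean[sig$set == "up" & sig$arm == "RESTED_D11_15"]
    ok <- all(diff(up_on) > 0) &&                  # rises with day
      up_rest[3] < up_rest[2] &&                   # reverses after rest
      abs(up_rest[3]) < abs(up_on[3])              # returns toward baseline
    if (ok) hits <- hits + 1L
  }
  expect_gte(hits, 95L)
})
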