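# Generators: degenerate cases, seed determinism, moment oracles and the
# latent-observable link.

test_that("no-signal configuration yields constant intensities", {
  panel <- default_marker_panel(sigma = 0, dropout = 0, load = 0,
                                context_load = 0)
  cfg <- sim_config(n_cells_per_arm_day = 50, seed = 3,
                    marker_panel = panel, submodes = null_submodes(),
                    gate_pos_prob = c(CAR = 1, CD8 = 1))
  sim <- simulate_cytometry(cfg)
  non_gate <- panel$marker[panel$role != "gate"]
  for (mk in non_gate) {
    expect_equal(unique(sim$events$data[[mk]]),
                 exp(panel$baseline[panel$marker == mk]),
                 tolerance = 1e-12)
  }
  # gate channels are constant too (all cells share one gate state)
  for (mk in c("CAR", "CD8", "CD4"))
    expect_length(unique(sim$events$data[[mk]]), 1L)
})

test_that("identical seeds reproduce identical event tables", {
  s1 <- simulate_cytometry(sim_config(n_cells_per_arm_day = 80, seed = 9))
  s2 <- simulate_cytometry(sim_config(n_cells_per_arm_day = 80, seed = 9))
  expect_identical(s1$events$data, s2$events$data)
  expect_identical(s1$truth, s2$truth)
  s3 <- simulate_cytometry(sim_config(n_cells_per_arm_day = 80, seed = 10))
  expect_false(identical(s1$events$data, s3$events$data))
})

test_that("marker log-intensity shifts by load_e times the program gap", {
  # pin e at 0.9 vs 0.1 with an extreme Beta concentration; PD1 carries
  # load_e = 2, so the mean log-intensity gap has oracle 2 * 0.8 = 1.6
  # two days so day 1 is pre-terminal and follows mu_e, not the attractors
  panel <- default_marker_panel(sigma = 0.3, dropout = 0)
  panel$load_e[panel$marker == "PD1"] <- 2
  arms <- list(
    arm_trajectory("HI", c(1, 2), mu_e = c(0.9, 0.5), mu_m = c(0.5, 0.5),
                   kappa = 1e6),
    arm_trajectory("LO", c(1, 2), mu_e = c(0.1, 0.5), mu_m = c(0.5, 0.5),
                   kappa = 1e6))
  sim <- simulate_cytometry(sim_config(n_cells_per_arm_day = 10000,
                                       seed = 4, marker_panel = panel,
                                       arms = arms,
                                       submodes = null_submodes()))
  d1 <- sim$events$data[sim$events$data$day == 1, ]
  lg <- log(d1$PD1)
  gap <- mean(lg[d1$arm == "HI"]) - mean(lg[d1$arm == "LO"])
  se <- 0.3 * sqrt(2 / 10000)
  expect_equal(gap, 1.6, tolerance = 5 * se / 1.6)
})

test_that("expected transformed intensity is monotone in e for loaded markers", {
  sim <- simulate_cytometry(sim_config(n_cells_per_arm_day = 2000, seed = 5))
  ev <- arcsinh_transform(sim$events, 5)
  e <- sim$truth$e
  bins <- cut(e, stats::quantile(e, seq(0, 1, 0.25)),
              include.lowest = TRUE)
  for (mk in c("PD1", "CD39", "TBET")) {
    means <- tapply(ev$data[[mk]], bins, mean)
    expect_true(all(diff(means) > 0), label = paste("monotone", mk))
  }
})

test_that("missing required channels are rejected by name", {
  panel <- default_marker_panel()
  panel <- panel[panel$marker != "TIM3", ]
  expect_error(sim_config(marker_panel = panel), "TIM3")
  bad <- default_marker_panel()
  expect_error(marker_model("X", 1, load_e = Inf), "non-finite")
})

test_that("bulk null generator equalizes group means across arms", {
  sim <- simulate_bulk_counts(effect_size = 0, n_genes = 400,
                              lib_range = c(1, 1), seed = 21)
  norm <- normalize_counts(sim$es)
  sig_genes <- sim$truth$gene[sim$truth$class == "up"]
  arm <- sim$es$samples$arm
  m_on <- rowMeans(norm[sig_genes, arm == "ALWAYS_ON"])
  m_off <- rowMeans(norm[sig_genes, arm == "ALWAYS_OFF"])
  # no systematic shift: mean gene-wise difference near 0
  expect_lt(abs(mean(m_on - m_off)), 0.05)
})

test_that("near-Poisson dispersion gives variance close to the mean", {
  design <- data.frame(sample_id = sprintf("s%04d", 1:2000),
                       arm = "ALWAYS_OFF", day = 7, donor = 1:2000,
                       program = 0)
  sim <- simulate_bulk_counts(design, n_genes = 110, nb_dispersion = 1e6,
                              lib_range = c(1, 1), seed = 8)
  v <- apply(sim$es$counts, 1, stats::var)
  mu <- rowMeans(sim$es$counts)
  # moment oracle: Var ~ mu for Poisson; 2000 draws give ~3% relative SE
  expect_lt(median(abs(v / mu - 1)), 0.1)
})

test_that("bulk and clonotype generators are seed-deterministic", {
  b1 <- simulate_bulk_counts(n_genes = 200, seed = 2)
  b2 <- simulate_bulk_counts(n_genes = 200, seed = 2)
  expect_identical(b1$es$counts, b2$es$counts)
  c1 <- simulate_clonotypes(n_clones = 100, depth = 5000, seed = 2)
  c2 <- simulate_clonotypes(n_clones = 100, depth = 5000, seed = 2)
  expect_identical(c1$tab$records, c2$tab$records)
})

test_that("clonotype truth matches closed forms and brute-force sums", {
  u <- simulate_clonotypes(n_clones = 4, power_alpha = 0, depth = 400,
                           arms = "A", seed = 1)
  expect_equal(u$truth$shannon_true, log(4), tolerance = 1e-12)
  expect_equal(u$truth$invsimpson_true, 4, tolerance = 1e-12)
  one <- simulate_clonotypes(n_clones = 1, power_alpha = 1, depth = 50,
                             arms = "A", seed = 1)
  expect_equal(one$truth$shannon_true, 0)
  expect_equal(one$truth$invsimpson_true, 1)
  # direct summation oracle at alpha = 1, 100 clones
  p <- (1 / (1:100)) / sum(1 / (1:100))
  z <- simulate_clonotypes(n_clones = 100, power_alpha = 1, depth = 10000,
                           arms = "A", seed = 1)
  expect_equal(z$truth$shannon_true, -sum(p * log(p)), tolerance = 1e-12)
  expect_equal(z$truth$invsimpson_true, 1 / sum(p^2), tolerance = 1e-12)
})

test_that("clonotype counts conserve the requested depth per arm", {
  sim <- simulate_clonotypes(n_clones = c(500, 20), power_alpha = c(1, 0.5),
                             depth = 12345, seed = 6)
  tot <- tapply(sim$tab$records$count, sim$tab$records$sample_id, sum)
  expect_true(all(tot == 12345))
})

test_that("zero-loading data produce no spurious score trend", {
  # type-I behaviour of the full generator -> score -> trend path
  panel <- default_marker_panel(load = 0, context_load = 0)
  rejections <- 0L
  n_rep <- 100
  for (r in seq_len(n_rep)) {
    sim <- simulate_cytometry(sim_config(n_cells_per_arm_day = 50,
                                         seed = 1000 + r,
                                         marker_panel = panel,
                                         submodes = null_submodes()))
    sc <- compute_scores(normalize_markers(arcsinh_transform(sim$events, 5)))
    on <- sc$meta$arm == "ALWAYS_ON"
    tr <- trend_test(sc$meta$day[on], sc$exhaustion_score[on],
                     n_perm = 999, seed = r)
    if (tr$p_perm <= 0.05) rejections <- rejections + 1L
  }
  # binomial(100, 0.05) stays at or below 12 with probability > 0.998
  expect_lte(rejections, 12L)
})
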