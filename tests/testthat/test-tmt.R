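test_that("channel normalization centres each channel median at zero", {
  m <- cbind(A = c(100, 200, 400))
  rownames(m) <- c("p1", "p2", "p3")
  expect_equal(unname(normalize_channels(m)[, "A"]), c(-1, 0, 1))

  # rescaling a channel by any positive constant changes nothing
  set.seed(1)
  m2 <- matrix(2^rnorm(60, 10), 20, 3,
               dimnames = list(sprintf("p%02d", 1:20), c("A", "B", "C")))
  n1 <- normalize_channels(m2)
  m3 <- m2
  m3[, "B"] <- m3[, "B"] * 8
  expect_equal(normalize_channels(m3), n1, tolerance = 1e-12)
  expect_equal(apply(n1, 2, median), c(A = 0, B = 0, C = 0), tolerance = 1e-12)
  # idempotence on already-centred data
  expect_equal(normalize_channels(2^n1), n1, tolerance = 1e-12)

  m_bad <- m
  m_bad[2, 1] <- -5
  expect_error(normalize_channels(m_bad), "p2",
               class = "dualquant_input_error")
})

test_that("ratios difference the matched control and skip control conditions", {
  design <- default_study_design()
  nm <- matrix(0, 3, 5, dimnames = list(c("p1", "p2", "p3"), design$conditions))
  nm["p1", "CPZ-42d"] <- 1
  nm["p1", "CTR-CPZ"] <- -1
  nm["p2", "EAE-16d"] <- NA
  r <- compute_ratios(nm, design)
  expect_setequal(unique(r$condition), design$disease)
  expect_equal(r$ratio[r$protein_id == "p1" & r$condition == "CPZ-42d"], 4)
  expect_equal(r$ratio[r$protein_id == "p2" & r$condition == "CPZ-42d"], 1)
  # proteins missing in a channel are dropped from that condition only
  expect_false("p2" %in% r$protein_id[r$condition == "EAE-16d"])
  expect_true("p2" %in% r$protein_id[r$condition == "EAE-32d"])
  expect_equal(r$ratio, 2^r$log2_ratio)

  bad_design <- design
  bad_design$control_map <- c(bad_design$control_map, "NEW" = "CTR-CPZ")
  bad_design$disease <- c(bad_design$disease, "NEW")
  expect_error(compute_ratios(nm, bad_design), "NEW",
               class = "dualquant_design_error")
})

test_that("Gaussian empirical-null z-scores give calibrated two-sided p-values", {
  r <- data.frame(protein_id = sprintf("p%d", 1:5), condition = "A",
                  log2_ratio = c(-2, -1, 0, 1, 2))
  s <- gaussian_z_pvalues(r)
  expect_equal(s$z[3], 0)
  expect_equal(s$p[3], 1)
  expect_equal(s$z, (r$log2_ratio - mean(r$log2_ratio)) / sd(r$log2_ratio))

  # a ratio landing exactly at mu_hat + 1.96 sigma_hat has p ~ 0.05: build a
  # symmetric vector (mean 0) whose probe pair sits at +-1.96 sd of the whole
  base <- seq(-1, 1, length.out = 99)
  S <- sum(base^2)
  t_probe <- sqrt(1.96^2 * S / 100 / (1 - 2 * 1.96^2 / 100))
  v <- c(base, -t_probe, t_probe)
  stopifnot(abs(t_probe - 1.96 * sd(v)) < 1e-12)
  r2 <- data.frame(protein_id = sprintf("p%d", seq_along(v)), condition = "A",
                   log2_ratio = v)
  s2 <- gaussian_z_pvalues(r2)
  expect_lt(abs(s2$p[length(v)] - 0.05), 0.001)

  # null simulation: ~5% of p-values below 0.05
  set.seed(3)
  r3 <- data.frame(protein_id = sprintf("p%d", 1:2000), condition = "A",
                   log2_ratio = rnorm(2000))
  s3 <- gaussian_z_pvalues(r3)
  expect_lt(abs(mean(s3$p < 0.05) - 0.05), 0.015)

  # robust estimator uses median / MAD
  s4 <- gaussian_z_pvalues(r3, robust = TRUE)
  expect_equal(s4$z,
               (r3$log2_ratio - median(r3$log2_ratio)) / mad(r3$log2_ratio))

  expect_error(gaussian_z_pvalues(r[1:2, ]), "fewer than 3",
               class = "dualquant_input_error")
  r_flat <- data.frame(protein_id = sprintf("p%d", 1:4), condition = "A",
                       log2_ratio = rep(0.3, 4))
  expect_error(gaussian_z_pvalues(r_flat), "zero spread",
               class = "dualquant_input_error")
})

test_that("BH adjustment matches hand-computed step-up values", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  p <- c(0.5, 0.01, 0.04, 0.04, 1)
  expect_equal(bh_adjust(p), bh_oracle(p))
  expect_error(bh_adjust(c(0.1, 0)), class = "dualquant_input_error")
  expect_error(bh_adjust(c(0.1, 1.2)), class = "dualquant_input_error")
})

test_that("BH equals the brute-force oracle on random vectors with ties", {
  set.seed(42)
  for (i in 1:100) {
    m <- sample(c(1:10, 50, 200), 1)
    p <- runif(m)
    if (m > 3) p[sample(m, 2)] <- p[1]  # force ties
    expect_identical(bh_adjust(p), bh_oracle(p))
  }
})

test_that("regulation calls combine the q cut-off with ratio direction", {
  s <- data.frame(log2_ratio = c(2, -1, 1, 0.5), q = c(1e-4, 1e-4, 0.2, 0.04))
  out <- classify_tmt_regulated(s, q_cut = 0.05)
  expect_identical(out$call, c("up", "down", "ns", "up"))
  expect_error(classify_tmt_regulated(s, q_cut = 0), "q_cut",
               class = "dualquant_config_error")
})

test_that("the pooled pipeline is invariant to channel rescaling end-to-end", {
  st <- simulate_study(sim_config(n_proteins = 300, seed = 8))
  t1 <- run_tmt(st$reporter)
  scaled <- st$reporter
  scaled[, "EAE-16d"] <- scaled[, "EAE-16d"] * 1000
  scaled[, "CTR-EAE"] <- scaled[, "CTR-EAE"] * 0.001
  t2 <- run_tmt(scaled)
  expect_equal(t1, t2, tolerance = 1e-9)
})

test_that("noise-free simulation feeds through to exact ratio recovery", {
  cfg <- noisefree_config(n = 400, frac = 0.05, seed = 5)
  st <- simulate_study(cfg)
  tmt <- run_tmt(st$reporter)
  expect_equal(tmt$log2fc, truth_effect_at(st$truth, tmt$protein_id, tmt$condition),
               tolerance = 1e-9)
})
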