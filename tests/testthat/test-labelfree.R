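test_that("run normalization removes global per-sample scale factors", {
  set.seed(10)
  base <- 2^matrix(rnorm(300, 15), 100, 3,
                   dimnames = list(sprintf("p%03d", 1:100), c("s1", "s2", "s3")))
  # identical samples: factors all 1
  same <- cbind(s1 = base[, 1], s2 = base[, 1], s3 = base[, 1])
  expect_equal(unname(attr(normalize_runs(same), "factors")), rep(1, 3))

  # one sample globally x3: its factor is 3 and it is restored exactly
  m <- base
  m[, "s2"] <- m[, "s2"] * 0  # rebuild as scaled copy of s1
  m[, "s2"] <- base[, 1] * 3
  nm <- normalize_runs(m)
  expect_equal(unname(attr(nm, "factors")["s2"]), 3)
  expect_equal(nm[, "s2"], base[, 1], ignore_attr = TRUE)

  # random per-sample scales on null data: post-hoc median log ratio is 0
  scales <- c(1, 0.2, 7.5)
  m2 <- sweep(cbind(base[, 1], base[, 1], base[, 1]), 2, scales, "*")
  colnames(m2) <- c("s1", "s2", "s3")
  nm2 <- normalize_runs(m2)
  ref <- attr(nm2, "reference")
  for (j in colnames(m2)) {
    expect_lt(abs(median(log2(nm2[, j] / nm2[, ref]))), 1e-9)
  }
  # idempotence
  expect_equal(normalize_runs(nm2), nm2, ignore_attr = TRUE, tolerance = 1e-12)

  m_bad <- base
  m_bad[5, 2] <- 0
  expect_error(normalize_runs(m_bad), class = "dualquant_input_error")
})

test_that("the reference run is the sample with fewest missing values", {
  set.seed(11)
  m <- 2^matrix(rnorm(60, 12), 20, 3,
                dimnames = list(sprintf("p%02d", 1:20), c("a", "b", "c")))
  m[1:5, "a"] <- NA
  m[1:2, "c"] <- NA
  expect_identical(attr(normalize_runs(m), "reference"), "b")
})

test_that("the pooled control is the union of all control animals", {
  design <- default_study_design()
  st <- simulate_labelfree(generate_truth(sim_config(n_proteins = 20, seed = 1)),
                           sim_config(n_proteins = 20, seed = 1))
  ctrl <- build_pooled_control(st$samples, design)
  expect_length(ctrl, 11)
  expect_setequal(unique(st$samples$condition[st$samples$sample_id %in% ctrl]),
                  c("CTR-CPZ", "CTR-EAE"))
  no_ctrl <- st$samples[!st$samples$condition %in% design$controls, ]
  expect_error(build_pooled_control(no_ctrl, design),
               class = "dualquant_design_error")
})

test_that("two-group ANOVA reproduces the pooled-variance t-test", {
  set.seed(12)
  for (i in 1:10) {
    y1 <- rnorm(5, 10)
    y2 <- rnorm(8, 10.5)
    m <- matrix(2^c(y1, y2), 1)
    p_anova <- anova_per_protein(m, rep(c("a", "b"), c(5, 8)))
    p_t <- t.test(y1, y2, var.equal = TRUE)$p.value
    expect_equal(unname(p_anova), p_t, tolerance = 1e-12)
  }
})

test_that("ANOVA handles missingness rules and degenerate inputs", {
  g <- rep(c("a", "b", "c"), each = 3)
  m <- matrix(2^rnorm(18, 10), 2, 9)
  m[1, 1:2] <- NA  # group a has a single observed value for protein 1
  p <- anova_per_protein(m, g)
  expect_true(is.na(p[1]))
  expect_false(is.na(p[2]))
  # all-identical values: p = 1 by convention
  m2 <- matrix(2^10, 1, 9)
  expect_equal(unname(anova_per_protein(m2, g)), 1)
  expect_error(anova_per_protein(m, rep("a", 9)), class = "dualquant_input_error")
})

test_that("ANOVA p-values are uniform under the null and powered under shift", {
  set.seed(13)
  g <- rep(c("a", "b", "c"), c(5, 5, 11))
  m_null <- matrix(2^rnorm(2000 * 21, 12, 0.5), 2000, 21)
  p_null <- anova_per_protein(m_null, g)
  expect_gt(ks.test(p_null, "punif")$p.value, 0.01)

  # power under a 3-SD shift of one group matches noncentral-F theory
  shift <- rep(c(0, 3 * 0.5, 0), c(5, 5, 11))
  m_alt <- 2^(matrix(rnorm(400 * 21, 12, 0.5), 400, 21) +
                matrix(shift, 400, 21, byrow = TRUE))
  p_alt <- anova_per_protein(m_alt, g)
  mu <- shift / 0.5                       # group means in SD units
  ncp <- sum(tapply(mu, g, length) * (tapply(mu, g, mean) - mean(mu))^2)
  power <- 1 - pf(qf(1 - 0.001, 2, 18), 2, 18, ncp = ncp)
  got <- mean(p_alt < 0.001)
  expect_lt(abs(got - power), 3 * sqrt(power * (1 - power) / 400) + 0.01)
  expect_gt(got, 0.9)
})

test_that("fold changes are ratios of group means of observed values", {
  design <- default_study_design()
  samples <- data.frame(
    sample_id = c("c1", "c2", "d1", "d2"),
    condition = c("CTR-CPZ", "CTR-EAE", "CPZ-42d", "CPZ-42d"))
  m <- matrix(c(2, 3, 4, 6), 1, 4,
              dimnames = list("p1", samples$sample_id))
  fc <- fold_changes(m, samples, design)
  expect_equal(fc$fc[fc$condition == "CPZ-42d"], 5 / 2.5)
  # hand case from a 2-vs-3 layout
  samples2 <- data.frame(sample_id = c("d1", "d2", "c1", "c2", "c3"),
                         condition = c("CPZ-42d", "CPZ-42d",
                                       "CTR-CPZ", "CTR-CPZ", "CTR-EAE"))
  m2 <- matrix(c(4, 6, 2, 3, 1), 1, 5,
               dimnames = list("p1", samples2$sample_id))
  fc2 <- fold_changes(m2, samples2, design)
  expect_equal(fc2$fc[fc2$condition == "CPZ-42d"], 2.5)
  # identical groups give FC 1; missing side gives NA
  m3 <- matrix(c(2, 2, 2, 2, 2), 1, 5,
               dimnames = list("p1", samples2$sample_id))
  expect_equal(fold_changes(m3, samples2, design)$fc[1], 1)
  m4 <- m2
  m4[1, 1:2] <- NA
  expect_true(is.na(fold_changes(m4, samples2, design)$fc[1]))
})

test_that("the significance cascade is the exact stated conjunction", {
  th <- cascade_thresholds()
  expect_identical(apply_cascade(4.9, 0.01, 0.01, "CPZ-42d", th), "up")
  expect_identical(apply_cascade(1.5, 1e-9, 1e-9, "CPZ-42d", th), "ns")
  # condition stratification: same q passes EAE-32d (0.11) but not CPZ (0.05)
  expect_identical(apply_cascade(0.5, 0.01, 0.09, "EAE-32d", th), "down")
  expect_identical(apply_cascade(0.5, 0.01, 0.09, "CPZ-42d", th), "ns")
  expect_error(apply_cascade(2, 0.01, 0.01, "nope", th),
               class = "dualquant_design_error")

  # crossing any single threshold flips the call
  eps <- 1e-9
  base <- list(fc = 2, p = 0.049, q = 0.049, cond = "CPZ-42d")
  expect_identical(apply_cascade(base$fc, base$p, base$q, base$cond, th), "up")
  expect_identical(apply_cascade(base$fc - eps, base$p, base$q, base$cond, th), "ns")
  expect_identical(apply_cascade(base$fc, 0.05, base$q, base$cond, th), "ns")
  expect_identical(apply_cascade(base$fc, base$p, 0.05, base$cond, th), "ns")
  expect_identical(apply_cascade(0.7, base$p, base$q, base$cond, th), "down")
  expect_identical(apply_cascade(0.7 + eps, base$p, base$q, base$cond, th), "ns")
})

test_that("noise-free label-free fold changes equal the encoded truth exactly", {
  cfg <- noisefree_config(n = 400, frac = 0.05, seed = 5)
  st <- simulate_study(cfg)
  lf <- run_labelfree(st$labelfree$values, st$labelfree$samples)
  expect_equal(lf$fc, 2^truth_effect_at(st$truth, lf$protein_id, lf$condition),
               tolerance = 1e-12)
})
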