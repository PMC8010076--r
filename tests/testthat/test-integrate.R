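test_that("quantified overlap is an exact set partition", {
  ov <- overlap_quantified(c("A", "B", "C"), c("B", "C", "D"))
  expect_setequal(ov$shared, c("B", "C"))
  expect_identical(unname(ov$counts), c(2L, 1L, 1L))
  expect_identical(overlap_quantified(letters, letters)$counts[["tmt_only"]], 0L)
  expect_identical(overlap_quantified(c("A"), c("B"))$counts[["shared"]], 0L)
  expect_identical(ov$counts[["shared"]] + ov$counts[["tmt_only"]], 3L)
})

make_calls <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    data.frame(protein_id = r[[1]], condition = r[[2]], fc = as.numeric(r[[3]]),
               q = as.numeric(r[[4]]), call = r[[5]], p = as.numeric(r[[4]]),
               log2fc = log2(as.numeric(r[[3]])), stringsAsFactors = FALSE)
  }))
}

test_that("verification requires same-direction significance on both platforms", {
  tmt <- make_calls(list("LGMN", "CPZ-42d", 4.0, 4e-4, "up"),
                    list("HEMO", "EAE-16d", 1.8, 4e-4, "up"),
                    list("X1", "CPZ-42d", 3.0, 1e-3, "up"),
                    list("X2", "CPZ-42d", 3.0, 1e-3, "up"),
                    list("X3", "CPZ-42d", 0.4, 1e-3, "down"))
  lf <- make_calls(list("LGMN", "CPZ-42d", 4.9, 0.04, "up"),
                   list("HEMO", "EAE-16d", 3.3, 0.04, "up"),
                   list("X1", "CPZ-42d", 1.2, 0.5, "ns"),
                   list("X2", "CPZ-42d", 3.1, 1e-3, "up"),
                   list("X3", "CPZ-42d", 2.5, 1e-3, "up"))
  v <- verify_regulated(tmt, lf)
  expect_setequal(v$protein_id, c("LGMN", "HEMO", "X2"))
  expect_identical(v$direction[v$protein_id == "LGMN"], "up")
  # discordant directions are excluded but reported
  disc <- attr(v, "discordant")
  expect_identical(disc$protein_id, "X3")
  # permutation invariance of membership
  perm <- sample(nrow(tmt))
  v2 <- verify_regulated(tmt[perm, ], lf[rev(seq_len(nrow(lf))), ])
  expect_identical(v2[order(v2$protein_id), ]$protein_id,
                   v[order(v$protein_id), ]$protein_id)
})

test_that("evidence weights follow the 1.2-fold dual-platform rule", {
  design <- default_study_design()
  tmt <- make_calls(list("A", "CPZ-42d", 1.5, 0.01, "ns"),
                    list("B", "CPZ-42d", 1.5, 0.01, "ns"),
                    list("C", "CPZ-42d", 1.5, 0.5, "ns"),
                    list("D", "CPZ-42d", 1.1, 0.01, "ns"))
  lf <- make_calls(list("A", "CPZ-42d", 1.5, 0.01, "ns"),
                   list("B", "CPZ-42d", 1.5, 0.5, "ns"),
                   list("C", "CPZ-42d", 1.5, 0.5, "ns"),
                   list("D", "CPZ-42d", 1.5, 0.01, "ns"))
  w <- assign_evidence_weights(tmt, lf, design)
  get <- function(id) w$weight[w$protein_id == id]
  expect_identical(get("A"), 0.005)  # both significant at >= 1.2-fold
  expect_identical(get("B"), 0.05)   # TMT only
  expect_true(is.na(get("C")))       # neither
  expect_identical(get("D"), 0.05)   # TMT significant but below 1.2-fold
  # the two weight groups are disjoint by construction
  expect_identical(intersect(w$protein_id[!is.na(w$weight) & w$weight == 0.005],
                             w$protein_id[!is.na(w$weight) & w$weight == 0.05]),
                   character(0))
})

test_that("the combined ratio matrix carries explicit gaps and fixed column order", {
  tmt <- make_calls(list("A", "CPZ-42d", 2, 0.5, "ns"),
                    list("A", "EAE-16d", 2, 0.5, "ns"),
                    list("A", "EAE-32d", 2, 0.5, "ns"),
                    list("B", "CPZ-42d", 4, 0.5, "ns"),
                    list("B", "EAE-16d", 4, 0.5, "ns"),
                    list("B", "EAE-32d", 4, 0.5, "ns"))
  lf <- make_calls(list("A", "CPZ-42d", 8, 0.5, "ns"),
                   list("A", "EAE-16d", 8, 0.5, "ns"),
                   list("A", "EAE-32d", 8, 0.5, "ns"))
  m <- combined_ratio_matrix(tmt, lf)
  expect_identical(colnames(m),
                   c("TMT:CPZ-42d", "TMT:EAE-16d", "TMT:EAE-32d",
                     "LF:CPZ-42d", "LF:EAE-16d", "LF:EAE-32d"))
  expect_equal(sum(is.finite(m["A", ])), 6L)
  expect_equal(sum(is.finite(m["B", ])), 3L)
  expect_equal(unname(m["A", "LF:CPZ-42d"]), 3)
})

test_that("column clustering joins identical columns first", {
  set.seed(20)
  a <- rnorm(30)
  mat <- cbind(A = a, B = a, C = rnorm(30))
  hc <- cluster_conditions(mat)
  # first merge is A with B at height 0
  expect_equal(sort(hc$merge[1, ]), c(-2, -1))
  expect_equal(hc$height[1], 0)
  expect_error(cluster_conditions(mat[1, , drop = FALSE]),
               class = "dualquant_input_error")
  expect_error(cluster_conditions(mat[, 1, drop = FALSE]),
               class = "dualquant_input_error")
})

test_that("ratio histograms are normalized, centred and symmetric", {
  h0 <- ratio_histogram(rep(0, 10), bin_width = 0.2)
  expect_identical(nrow(h0), 1L)
  expect_equal(h0$freq, 1)
  expect_equal(h0$center, 0)

  x <- c(-1.04, -0.54, -0.04, 0.04, 0.54, 1.04)
  h <- ratio_histogram(x, bin_width = 0.1)
  expect_equal(sum(h$freq), 1)
  expect_equal(h$count, rev(h$count))

  set.seed(21)
  h2 <- ratio_histogram(rnorm(2000, 0, 0.25), bin_width = 0.1)
  expect_lte(abs(h2$center[which.max(h2$freq)]), 0.1)
  expect_error(ratio_histogram(numeric(0)), class = "dualquant_input_error")
})

test_that("verified records have the spiked direction on truth-bearing runs", {
  hits <- 0; total <- 0
  for (s in 1:3) {
    st <- simulate_study(sim_config(n_proteins = 800, seed = 100 + s))
    fit <- dualquant(st$reporter, st$labelfree$values, st$labelfree$samples,
                     cluster = FALSE)
    eff <- truth_effect_at(st$truth, fit$verified$protein_id,
                           fit$verified$condition)
    hits <- hits + sum((eff > 0 & fit$verified$direction == "up") |
                         (eff < 0 & fit$verified$direction == "down"))
    total <- total + nrow(fit$verified)
  }
  expect_gt(total, 0)
  expect_gte(hits / total, 0.95)
})
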