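#' Fit the dual-platform differential abundance analysis
#'
#' The package's central function: runs the pooled-channel pipeline
#' ([run_tmt()]) and the per-animal label-free pipeline ([run_labelfree()]),
#' then integrates them — quantified-protein overlap, cross-platform
#' verification of regulated proteins, evidence weights for pathway-tool
#' input, the combined log2-ratio matrix and its condition clustering.
#'
#' @param reporter proteins x conditions linear reporter-intensity matrix.
#' @param values proteins x samples linear label-free abundance matrix
#'   (`NA` = missing).
#' @param samples sample sheet (`sample_id`, `condition`) for `values`.
#' @param design a `dq_design`; defaults to [default_study_design()].
#' @param robust_z use the robust (median/MAD) empirical null on the pooled
#'   platform.
#' @param cluster also cluster the combined ratio matrix (skipped silently if
#'   too few complete rows).
#' @return an object of class `dualquant`: list with components `tmt`,
#'   `labelfree` (per-platform differential tables), `overlap`, `verified`,
#'   `weights`, `combined` (log2-ratio matrix), `clustering` (`hclust` or
#'   `NULL`), `design` and `call`.
#' @seealso [summary.dualquant()], [plot.dualquant()],
#'   [score_against_truth()].
#' @export
#' @examples
#' study <- simulate_study(sim_config(n_proteins = 400, seed = 11))
#' fit <- dualquant(study$reporter, study$labelfree$values,
#'                  study$labelfree$samples)
#' summary(fit)
dualquant <- function(reporter, values, samples,
                      design = default_study_design(),
                      robust_z = FALSE, cluster = TRUE) {
  tmt <- run_tmt(reporter, design, robust = robust_z)
  lf <- run_labelfree(values, samples, design)
  ov <- overlap_quantified(rownames(reporter), rownames(values))
  verified <- verify_regulated(tmt, lf)
  verified <- verified[verified$protein_id %in% ov$shared, , drop = FALSE]
  weights <- assign_evidence_weights(tmt, lf, design)
  combined <- combined_ratio_matrix(tmt, lf)
  clustering <- NULL
  if (cluster) {
    # cluster the regulated protein list (the usual heat-map input); rows of
    # pure noise would otherwise be inflated to unit variance by the row
    # z-scoring and drown the condition structure
    reg_ids <- union(tmt$protein_id[tmt$call != "ns"],
                     lf$protein_id[lf$call != "ns"])
    clustering <- tryCatch(
      cluster_conditions(combined[rownames(combined) %in% reg_ids, , drop = FALSE]),
      dualquant_input_error = function(e) NULL)
  }
  structure(list(tmt = tmt, labelfree = lf, overlap = ov, verified = verified,
                 weights = weights, combined = combined,
                 clustering = clustering, design = design,
                 call = match.call()),
            class = "dualquant")
}

#' @export
print.dualquant <- function(x, ...) {
  cat("Dual-platform differential abundance analysis\n")
  cat(sprintf("  quantified: %d pooled-channel, %d label-free, %d shared\n",
              x$overlap$counts[["shared"]] + x$overlap$counts[["tmt_only"]],
              x$overlap$counts[["shared"]] + x$overlap$counts[["lf_only"]],
              x$overlap$counts[["shared"]]))
  cat(sprintf("  verified regulated records: %d\n", nrow(x$verified)))
  invisible(x)
}

#' Summarize a dual-platform fit
#'
#' Per-condition regulation counts on each platform and in the verified set.
#'
#' @param object a `dualquant` fit.
#' @param ... unused.
#' @return a `summary.dualquant` object (list of count tables), printed as a
#'   compact report.
#' @export
summary.dualquant <- function(object, ...) {
  count_calls <- function(df) {
    tab <- table(factor(df$call, levels = c("up", "down", "ns")), df$condition)
    tab[c("up", "down"), , drop = FALSE]
  }
  verified <- if (nrow(object$verified)) {
    table(factor(object$verified$direction, levels = c("up", "down")),
          object$verified$condition)
  } else NULL
  structure(list(overlap = object$overlap$counts,
                 tmt = count_calls(object$tmt),
                 labelfree = count_calls(object$labelfree),
                 verified = verified,
                 n_discordant = nrow(attr(object$verified, "discordant") %||%
                                       data.frame())),
            class = "summary.dualquant")
}

#' @export
print.summary.dualquant <- function(x, ...) {
  cat("Quantified-protein overlap:\n")
  print(x$overlap)
  cat("\nPooled-channel regulation calls:\n")
  print(x$tmt)
  cat("\nLabel-free regulation calls:\n")
  print(x$labelfree)
  cat("\nVerified (both platforms, same direction):\n")
  if (is.null(x$verified)) cat("  none\n") else print(x$verified)
  if (x$n_discordant > 0)
    cat(sprintf("\n%d discordant-direction pair(s) excluded\n", x$n_discordant))
  invisible(x)
}

#' Extract the combined cross-platform log2-ratio matrix
#'
#' @param object a `dualquant` fit.
#' @param ... unused.
#' @return the proteins x (platform, condition) log2-ratio matrix.
#' @export
coef.dualquant <- function(object, ...) object$combined

#' Plot a dual-platform fit
#'
#' Left: relative-frequency distributions of each condition's log2 ratios per
#' platform (the classic normalization sanity check — unimodal, centred near
#' zero). Right: the condition dendrogram, when available.
#'
#' @param x a `dualquant` fit.
#' @param bin_width histogram bin width in log2 units.
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.dualquant <- function(x, bin_width = 0.1, ...) {
  op <- graphics::par(mfrow = c(1, if (is.null(x$clustering)) 1 else 2))
  on.exit(graphics::par(op))
  conds <- x$design$disease
  cols <- grDevices::hcl.colors(length(conds), "Dark 3")
  hists <- lapply(conds, function(cond) {
    ratio_histogram(x$tmt$log2fc[x$tmt$condition == cond], bin_width)
  })
  xr <- range(unlist(lapply(hists, `[[`, "center")))
  yr <- c(0, max(unlist(lapply(hists, `[[`, "freq"))))
  graphics::plot(NA, xlim = xr, ylim = yr, xlab = "log2 ratio vs control",
                 ylab = "relative frequency",
                 main = "Pooled-channel ratio distributions", ...)
  for (i in seq_along(conds)) {
    graphics::lines(hists[[i]]$center, hists[[i]]$freq, col = cols[i], lwd = 2)
  }
  graphics::legend("topright", legend = conds, col = cols, lwd = 2, bty = "n")
  if (!is.null(x$clustering)) {
    graphics::plot(x$clustering, main = "Condition clustering", xlab = "",
                   sub = "")
  }
  invisible(x)
}

#' Benchmark calls against simulation ground truth
#'
#' Scores a verified-record table (or a `dualquant` fit) against the truth
#' table that generated the data, at (protein, condition) resolution:
#' sensitivity = correctly-directed calls / truly regulated pairs; false
#' discovery proportion = calls on truly-null pairs / all calls (0 when there
#' are no calls); direction accuracy = correctly-directed calls / calls on
#' truly regulated pairs.
#'
#' @param x a `dualquant` fit or a verified-record data frame
#'   (`protein_id`, `condition`, `direction`).
#' @param truth the [generate_truth()] table behind the data.
#' @return list of class `dq_benchmark`: `sensitivity`, `fdp`,
#'   `direction_accuracy`, `n_true`, `n_called`, `n_correct`, `n_null_called`.
#' @export
#' @examples
#' study <- simulate_study(sim_config(n_proteins = 400, seed = 11))
#' fit <- dualquant(study$reporter, study$labelfree$values,
#'                  study$labelfree$samples)
#' score_against_truth(fit, study$truth)
score_against_truth <- function(x, truth) {
  calls <- if (inherits(x, "dualquant")) x$verified else x
  stopifnot(all(c("protein_id", "condition", "direction") %in% names(calls)))
  if (!inherits(truth, "dq_truth")) input_error("truth must come from generate_truth()")
  missing_p <- setdiff(calls$protein_id, rownames(truth$effects))
  if (length(missing_p))
    input_error("called protein absent from truth: %s", missing_p[1])
  missing_c <- setdiff(calls$condition, colnames(truth$effects))
  if (length(missing_c))
    input_error("called condition absent from truth: %s", missing_c[1])
  eff <- truth$effects[cbind(match(calls$protein_id, rownames(truth$effects)),
                             match(calls$condition, colnames(truth$effects)))]
  n_true <- sum(truth$effects != 0)
  n_called <- nrow(calls)
  correct <- (eff > 0 & calls$direction == "up") |
    (eff < 0 & calls$direction == "down")
  n_null_called <- sum(eff == 0)
  structure(list(
    sensitivity = if (n_true > 0) sum(correct) / n_true else NA_real_,
    fdp = if (n_called > 0) n_null_called / n_called else 0,
    direction_accuracy = if (sum(eff != 0) > 0) sum(correct) / sum(eff != 0)
                         else NA_real_,
    n_true = n_true, n_called = n_called, n_correct = sum(correct),
    n_null_called = n_null_called
  ), class = "dq_benchmark")
}

#' @export
print.dq_benchmark <- function(x, ...) {
  cat(sprintf(
    "Benchmark vs truth: sensitivity %.3f, FDP %.3f, direction accuracy %s\n",
    x$sensitivity, x$fdp,
    if (is.na(x$direction_accuracy)) "NA" else sprintf("%.3f", x$direction_accuracy)))
  cat(sprintf("  (%d truly regulated pairs, %d called, %d correct, %d null called)\n",
              x$n_true, x$n_called, x$n_correct, x$n_null_called))
  invisible(x)
}
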