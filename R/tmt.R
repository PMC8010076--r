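#' Median-centre reporter channels on the log2 scale
#'
#' Log2-transforms a strictly positive reporter-intensity matrix and subtracts
#' each channel's median over the proteins quantified in that channel, so the
#' per-channel median of the output is exactly zero. This removes per-channel
#' loading/labelling offsets; any multiplicative rescaling of a channel leaves
#' the result unchanged.
#'
#' @param m numeric matrix, proteins x channels, linear-scale intensities
#'   (strictly positive; `NA` allowed and ignored in the median).
#' @return matrix of median-centred log2 intensities.
#' @export
#' @examples
#' normalize_channels(cbind(A = c(100, 200, 400)))  # -1, 0, +1
normalize_channels <- function(m) {
  if (!is.matrix(m) || !is.numeric(m))
    input_error("reporter matrix must be a numeric matrix")
  bad <- which(!is.na(m) & m <= 0, arr.ind = TRUE)
  if (nrow(bad)) {
    input_error("non-positive intensity for protein '%s' in channel '%s'",
                rownames(m)[bad[1, 1]] %||% bad[1, 1],
                colnames(m)[bad[1, 2]] %||% bad[1, 2])
  }
  lg <- log2(m)
  med <- apply(lg, 2, stats::median, na.rm = TRUE)
  sweep(lg, 2, med)
}

#' Ratio each disease condition to its matched control
#'
#' On the median-centred log2 scale, the ratio is a difference:
#' `log2_ratio(p, c) = normalized(p, c) - normalized(p, control(c))`. Control
#' conditions emit no rows; proteins missing in either channel of a pair are
#' dropped from that condition's ratio set.
#'
#' @param normalized matrix from [normalize_channels()]; columns named by
#'   condition.
#' @param design a `dq_design`; every disease condition must have a column and
#'   so must its control.
#' @return data frame with columns `protein_id`, `condition`, `log2_ratio`,
#'   `ratio` (linear scale, `2^log2_ratio`).
#' @export
compute_ratios <- function(normalized, design) {
  if (!inherits(design, "dq_design")) design_error("design must be a dq_design")
  need <- unique(c(design$disease, design$control_map[design$disease]))
  miss <- setdiff(need, colnames(normalized))
  if (length(miss))
    design_error("condition without a channel in the matrix: %s",
                 paste(miss, collapse = ", "))
  ids <- rownames(normalized) %||% as.character(seq_len(nrow(normalized)))
  out <- lapply(design$disease, function(cond) {
    lr <- normalized[, cond] - normalized[, design$control_map[[cond]]]
    keep <- is.finite(lr)
    data.frame(protein_id = ids[keep], condition = cond,
               log2_ratio = unname(lr[keep]), ratio = unname(2^lr[keep]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Gaussian empirical-null z-scores and p-values for log2 ratios
#'
#' The pooled design has no replicates, so significance is assessed against
#' an empirical Gaussian null fitted to the whole distribution of a
#' condition's log2 ratios: `z = (log2_ratio - mu) / sigma` with `mu`, `sigma`
#' the sample mean and SD (or median and MAD when `robust = TRUE`), and
#' two-sided p-values `2 * (1 - pnorm(|z|))`. This treats the bulk of
#' proteins as unregulated and flags the tails.
#'
#' @param ratios data frame from [compute_ratios()] (any subset of conditions).
#' @param conditions conditions to score; default all present.
#' @param robust use median / MAD location-scale estimates instead of
#'   mean / SD.
#' @return `ratios` with columns `z` and `p` appended.
#' @export
gaussian_z_pvalues <- function(ratios, conditions = unique(ratios$condition),
                               robust = FALSE) {
  stopifnot(all(c("protein_id", "condition", "log2_ratio") %in% names(ratios)))
  out <- lapply(conditions, function(cond) {
    r <- ratios[ratios$condition == cond, , drop = FALSE]
    x <- r$log2_ratio
    if (length(x) < 3)
      input_error("condition '%s' has fewer than 3 ratios", cond)
    mu <- if (robust) stats::median(x) else mean(x)
    sigma <- if (robust) stats::mad(x) else stats::sd(x)
    if (!is.finite(sigma) || sigma == 0)
      input_error("degenerate ratio distribution in condition '%s' (zero spread)", cond)
    r$z <- (x - mu) / sigma
    r$p <- 2 * stats::pnorm(-abs(r$z))
    r$p <- pmin(pmax(r$p, .Machine$double.xmin), 1)
    r
  })
  do.call(rbind, out)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment: after validation this calls
#' `stats::p.adjust(method = "BH")`, i.e. `q(i) = min over j >= i of
#' p(j) * m / j` on the ascending sort, clipped to 1 and returned in input
#' order. Tied p-values receive identical q-values and `q >= p` elementwise.
#'
#' @param p numeric vector of p-values in (0, 1].
#' @return q-values, same length and order as `p`.
#' @export
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
bh_adjust <- function(p) {
  if (!is.numeric(p)) input_error("p-values must be numeric")
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1))
    input_error("p-values must lie in (0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Call regulation on the pooled platform
#'
#' `"up"` when `q < q_cut` and the log2 ratio is positive, `"down"` when
#' `q < q_cut` and it is negative, otherwise `"ns"`.
#'
#' @param stats data frame with columns `log2_ratio` and `q`.
#' @param q_cut BH q cut-off in (0, 1).
#' @return `stats` with a `call` column appended.
#' @export
classify_tmt_regulated <- function(stats, q_cut = 0.05) {
  if (!is_prob(q_cut) || q_cut <= 0 || q_cut >= 1)
    config_error("q_cut", "must be in (0, 1)")
  stopifnot(all(c("log2_ratio", "q") %in% names(stats)))
  stats$call <- ifelse(stats$q < q_cut & stats$log2_ratio > 0, "up",
                ifelse(stats$q < q_cut & stats$log2_ratio < 0, "down", "ns"))
  stats
}

#' Run the pooled-platform differential pipeline
#'
#' normalize -> ratio to matched control -> Gaussian empirical-null z and p
#' per condition -> BH q within each condition -> regulation call.
#'
#' @param reporter proteins x conditions linear reporter matrix (columns named
#'   by condition).
#' @param design a `dq_design`.
#' @param q_cut BH q cut-off for the call; defaults to `design$tmt_q_cut`.
#' @param robust passed to [gaussian_z_pvalues()].
#' @return data frame with columns `protein_id`, `condition`, `fc`, `log2fc`,
#'   `z`, `p`, `q`, `call`.
#' @export
#' @examples
#' study <- simulate_study(sim_config(n_proteins = 300, seed = 2))
#' head(run_tmt(study$reporter, default_study_design()))
run_tmt <- function(reporter, design = default_study_design(),
                    q_cut = design$tmt_q_cut, robust = FALSE) {
  normalized <- normalize_channels(reporter)
  ratios <- compute_ratios(normalized, design)
  stats <- gaussian_z_pvalues(ratios, conditions = design$disease, robust = robust)
  stats <- do.call(rbind, lapply(split(stats, stats$condition), function(r) {
    r$q <- bh_adjust(r$p)
    r
  }))
  stats <- classify_tmt_regulated(stats, q_cut)
  out <- data.frame(protein_id = stats$protein_id, condition = stats$condition,
                    fc = stats$ratio, log2fc = stats$log2_ratio,
                    z = stats$z, p = stats$p, q = stats$q, call = stats$call,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[order(out$condition, out$protein_id), , drop = FALSE]
}
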