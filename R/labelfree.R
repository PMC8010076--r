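#' Normalize label-free runs by median log-ratio scaling
#'
#' Each sample is rescaled by a single multiplicative factor so that the
#' median log2 ratio of its observed values to a reference run is zero. The
#' reference is the sample with the fewest missing values (ties broken by
#' column order). This is the usual global-scaling correction for per-run
#' loading differences; `method = "total"` offers plain total-intensity
#' scaling instead. Idempotent: normalizing twice equals normalizing once.
#'
#' @param values proteins x samples linear matrix, `NA` = missing, observed
#'   values strictly positive.
#' @param method `"median_ratio"` (default) or `"total"`.
#' @return normalized matrix with attributes `"factors"` (the divisors
#'   applied) and `"reference"` (reference sample name).
#' @export
normalize_runs <- function(values, method = c("median_ratio", "total")) {
  method <- match.arg(method)
  if (!is.matrix(values) || !is.numeric(values) || ncol(values) < 1)
    input_error("abundance matrix must be a numeric matrix with >= 1 sample")
  bad <- which(!is.na(values) & values <= 0, arr.ind = TRUE)
  if (nrow(bad))
    input_error("non-positive abundance for protein '%s' in sample '%s'",
                rownames(values)[bad[1, 1]] %||% bad[1, 1],
                colnames(values)[bad[1, 2]] %||% bad[1, 2])
  ref <- which.min(colSums(is.na(values)))
  factors <- vapply(seq_len(ncol(values)), function(j) {
    if (method == "total") {
      shared <- !is.na(values[, j]) & !is.na(values[, ref])
      if (!any(shared)) input_error("sample %d shares no observed proteins with the reference", j)
      sum(values[shared, j]) / sum(values[shared, ref])
    } else {
      lr <- log2(values[, j]) - log2(values[, ref])
      lr <- lr[is.finite(lr)]
      if (!length(lr)) input_error("sample %d shares no observed proteins with the reference", j)
      2^stats::median(lr)
    }
  }, numeric(1))
  out <- sweep(values, 2, factors, "/")
  attr(out, "factors") <- stats::setNames(factors, colnames(values))
  attr(out, "reference") <- colnames(values)[ref] %||% ref
  out
}

#' Pool all control samples into one CTR group
#'
#' The label-free comparison ratios every disease condition against a single
#' pooled control made of all control-condition animals.
#'
#' @param samples sample sheet (`sample_id`, `condition`).
#' @param design a `dq_design`.
#' @return character vector of control sample ids.
#' @export
build_pooled_control <- function(samples, design) {
  if (!inherits(design, "dq_design")) design_error("design must be a dq_design")
  ids <- samples$sample_id[samples$condition %in% design$controls]
  if (!length(ids)) design_error("no control samples present")
  ids
}

#' Per-protein one-way ANOVA p-values
#'
#' Classical fixed-effects one-way ANOVA (F-test, `stats::oneway.test` with
#' `var.equal = TRUE`) on log2 abundances, computed per protein over observed
#' values. A protein enters the test only if every compared group has at
#' least `min_obs` observed values; otherwise its p is `NA`. A protein whose
#' observed values are all identical gets p = 1 (zero between- and
#' within-group variance).
#'
#' @param values proteins x samples linear matrix (`NA` = missing).
#' @param groups factor/character of group membership per column.
#' @param min_obs minimum observed values per group (default 2).
#' @param log2_transform analyse log2 abundances (default) or linear values.
#' @return numeric vector of p-values, one per protein (`NA` = not testable).
#' @export
anova_per_protein <- function(values, groups, min_obs = 2, log2_transform = TRUE) {
  if (length(groups) != ncol(values))
    input_error("groups must have one entry per sample column")
  g <- factor(groups)
  if (nlevels(g) < 2) input_error("need at least 2 groups")
  x <- if (log2_transform) log2(values) else values
  apply(x, 1, function(y) {
    ok <- is.finite(y)
    cnt <- table(g[ok])
    if (length(cnt) < nlevels(g) || any(cnt < min_obs)) return(NA_real_)
    yy <- y[ok]
    if (max(yy) - min(yy) == 0) return(1)
    p <- stats::oneway.test(yy ~ g[ok], var.equal = TRUE)$p.value
    # infinite F (zero within-group variance) gives p = 0; keep p in (0, 1]
    max(p, .Machine$double.xmin)
  })
}

#' Fold changes of disease conditions over the pooled control
#'
#' Per protein and condition: the arithmetic mean of normalized linear
#' abundances in the condition divided by the mean in the pooled control,
#' over observed values. `NA` when a side has no observed value.
#'
#' @param values normalized proteins x samples linear matrix.
#' @param samples sample sheet (`sample_id`, `condition`).
#' @param design a `dq_design`.
#' @param control_ids pooled-control sample ids, see [build_pooled_control()].
#' @return data frame `protein_id`, `condition`, `fc`, `n_obs_cond`,
#'   `n_obs_ctrl`.
#' @export
fold_changes <- function(values, samples, design,
                         control_ids = build_pooled_control(samples, design)) {
  ids <- rownames(values) %||% as.character(seq_len(nrow(values)))
  ctrl <- values[, samples$sample_id %in% control_ids, drop = FALSE]
  ctrl_mean <- rowMeans(ctrl, na.rm = TRUE)
  n_ctrl <- rowSums(!is.na(ctrl))
  out <- lapply(design$disease, function(cond) {
    sel <- samples$sample_id[samples$condition == cond]
    cm <- values[, colnames(values) %in% sel, drop = FALSE]
    cond_mean <- rowMeans(cm, na.rm = TRUE)
    n_cond <- rowSums(!is.na(cm))
    fc <- ifelse(n_cond >= 1 & n_ctrl >= 1, cond_mean / ctrl_mean, NA_real_)
    data.frame(protein_id = ids, condition = cond, fc = unname(fc),
               n_obs_cond = unname(n_cond), n_obs_ctrl = unname(n_ctrl),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Apply the label-free significance cascade
#'
#' The regulation call is the exact conjunction: `"up"` iff
#' `fc >= fc_up & p < p_max & q < q_max[condition]`; `"down"` iff
#' `fc <= fc_down & p < p_max & q < q_max[condition]`; otherwise `"ns"`.
#' Fold changes inside the dead band (`fc_down`, `fc_up`) are never called
#' regardless of significance. Vectorized over its first four arguments.
#'
#' @param fc linear fold change over the pooled control.
#' @param p ANOVA p-value.
#' @param q BH q-value.
#' @param condition condition name (indexes `thresholds$q_max`).
#' @param thresholds a [cascade_thresholds()] object.
#' @return character vector of calls in `"up"`, `"down"`, `"ns"`.
#' @export
#' @examples
#' th <- cascade_thresholds()
#' apply_cascade(c(4.9, 1.5), c(0.01, 0.01), c(0.01, 0.01),
#'               c("CPZ-42d", "CPZ-42d"), th)
apply_cascade <- function(fc, p, q, condition, thresholds = cascade_thresholds()) {
  if (!inherits(thresholds, "dq_thresholds"))
    config_error("thresholds", "must be built with cascade_thresholds()")
  unknown <- setdiff(unique(condition), names(thresholds$q_max))
  if (length(unknown))
    design_error("no q cut-off for condition: %s", paste(unknown, collapse = ", "))
  qm <- unname(thresholds$q_max[condition])
  sig <- !is.na(fc) & !is.na(p) & !is.na(q) & p < thresholds$p_max & q < qm
  unname(ifelse(sig & fc >= thresholds$fc_up, "up",
                ifelse(sig & fc <= thresholds$fc_down, "down", "ns")))
}

#' Run the per-animal label-free differential pipeline
#'
#' run normalization -> pooled control -> per-protein omnibus one-way ANOVA
#' across disease groups plus pooled CTR (one p per protein) -> BH q across
#' proteins with a valid p -> per-condition fold change -> significance
#' cascade.
#'
#' @param values proteins x samples linear abundance matrix (`NA` = missing).
#' @param samples sample sheet (`sample_id`, `condition`) matching the
#'   columns.
#' @param design a `dq_design`.
#' @param normalize run [normalize_runs()] first (default `TRUE`).
#' @param log2_transform analyse log2 abundances in the ANOVA (default).
#' @return data frame `protein_id`, `condition`, `fc`, `p`, `q`, `call`,
#'   `n_obs_cond`, `n_obs_ctrl`.
#' @export
#' @examples
#' study <- simulate_study(sim_config(n_proteins = 300, seed = 2))
#' lf <- run_labelfree(study$labelfree$values, study$labelfree$samples)
#' table(lf$call, lf$condition)
run_labelfree <- function(values, samples, design = default_study_design(),
                          normalize = TRUE, log2_transform = TRUE) {
  if (!all(colnames(values) == samples$sample_id))
    input_error("sample sheet does not match matrix columns")
  extra <- setdiff(unique(samples$condition), design$conditions)
  if (length(extra))
    design_error("sample sheet contains unknown condition: %s",
                 paste(extra, collapse = ", "))
  if (normalize) values <- normalize_runs(values)
  control_ids <- build_pooled_control(samples, design)
  groups <- ifelse(samples$sample_id %in% control_ids, "CTR", samples$condition)
  p <- anova_per_protein(values, groups, log2_transform = log2_transform)
  q <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  q[ok] <- bh_adjust(p[ok])
  fc <- fold_changes(values, samples, design, control_ids)
  idx <- match(fc$protein_id, rownames(values) %||% as.character(seq_len(nrow(values))))
  fc$p <- p[idx]
  fc$q <- q[idx]
  fc$call <- rep("ns", nrow(fc))
  testable <- !is.na(fc$p)
  fc$call[testable] <- apply_cascade(fc$fc[testable], fc$p[testable],
                                     fc$q[testable], fc$condition[testable],
                                     design$thresholds)
  out <- fc[, c("protein_id", "condition", "fc", "p", "q", "call",
                "n_obs_cond", "n_obs_ctrl")]
  rownames(out) <- NULL
  out[order(out$condition, out$protein_id), , drop = FALSE]
}
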