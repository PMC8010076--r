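#' Overlap of quantified proteins between the two platforms
#'
#' @param tmt_ids accessions quantified on the pooled platform.
#' @param lf_ids accessions quantified on the label-free platform.
#' @return list with `shared`, `tmt_only`, `lf_only` (character vectors) and
#'   `counts` (named integer vector).
#' @export
overlap_quantified <- function(tmt_ids, lf_ids) {
  tmt_ids <- unique(tmt_ids)
  lf_ids <- unique(lf_ids)
  shared <- intersect(tmt_ids, lf_ids)
  tmt_only <- setdiff(tmt_ids, lf_ids)
  lf_only <- setdiff(lf_ids, tmt_ids)
  list(shared = shared, tmt_only = tmt_only, lf_only = lf_only,
       counts = c(shared = length(shared), tmt_only = length(tmt_only),
                  lf_only = length(lf_only)))
}

#' Cross-platform verification of regulated proteins
#'
#' The most trustworthy changes are those called significantly regulated in
#' the same direction by both platforms. A verified record is emitted for a
#' (protein, condition) pair iff both platforms quantified the protein and
#' both call it `"up"` or both call it `"down"`. Pairs called in opposite
#' directions are excluded and returned in the `"discordant"` attribute.
#'
#' @param tmt differential table from [run_tmt()].
#' @param lf differential table from [run_labelfree()].
#' @return data frame `protein_id`, `condition`, `tmt_fc`, `tmt_q`, `lf_fc`,
#'   `lf_q`, `direction`; attribute `"discordant"` holds excluded
#'   opposite-direction pairs.
#' @export
verify_regulated <- function(tmt, lf) {
  m <- merge(tmt[, c("protein_id", "condition", "fc", "q", "call")],
             lf[, c("protein_id", "condition", "fc", "q", "call")],
             by = c("protein_id", "condition"), suffixes = c("_tmt", "_lf"))
  both <- m$call_tmt != "ns" & m$call_lf != "ns"
  agree <- both & m$call_tmt == m$call_lf
  disc <- m[both & !agree, c("protein_id", "condition", "call_tmt", "call_lf")]
  out <- data.frame(protein_id = m$protein_id[agree],
                    condition = m$condition[agree],
                    tmt_fc = m$fc_tmt[agree], tmt_q = m$q_tmt[agree],
                    lf_fc = m$fc_lf[agree], lf_q = m$q_lf[agree],
                    direction = m$call_tmt[agree],
                    stringsAsFactors = FALSE)
  out <- out[order(out$condition, out$protein_id), , drop = FALSE]
  rownames(out) <- NULL
  rownames(disc) <- NULL
  attr(out, "discordant") <- disc
  out
}

#' Evidence weights for pathway-tool input
#'
#' Converts the two platforms' results into the weighting scheme used to feed
#' pathway analysis: weight 0.005 when a protein is statistically significant
#' with more than `fold`-fold change (default 1.2) on both platforms for the
#' condition, 0.05 when on exactly one, `NA` otherwise. Note the fold
#' criterion here is the relaxed pathway-input one, not the label-free
#' cascade's 2.0/0.7 dead band.
#'
#' @param tmt differential table from [run_tmt()].
#' @param lf differential table from [run_labelfree()].
#' @param design a `dq_design` (supplies the significance cut-offs).
#' @param fold minimum fold change (linear; a protein passes with
#'   `fc >= fold` or `fc <= 1/fold`).
#' @return data frame `protein_id`, `condition`, `weight`.
#' @export
assign_evidence_weights <- function(tmt, lf, design = default_study_design(),
                                    fold = 1.2) {
  m <- merge(tmt[, c("protein_id", "condition", "fc", "q")],
             lf[, c("protein_id", "condition", "fc", "p", "q")],
             by = c("protein_id", "condition"), suffixes = c("_tmt", "_lf"),
             all = TRUE)
  fold_ok <- function(fc) !is.na(fc) & (fc >= fold | fc <= 1 / fold)
  tmt_pass <- !is.na(m$q_tmt) & m$q_tmt < design$tmt_q_cut & fold_ok(m$fc_tmt)
  qm <- design$thresholds$q_max[m$condition]
  lf_pass <- !is.na(m$p) & !is.na(m$q_lf) &
    m$p < design$thresholds$p_max & m$q_lf < qm & fold_ok(m$fc_lf)
  n_pass <- tmt_pass + lf_pass
  data.frame(protein_id = m$protein_id, condition = m$condition,
             weight = ifelse(n_pass == 2, 0.005,
                             ifelse(n_pass == 1, 0.05, NA_real_)),
             stringsAsFactors = FALSE)
}

#' Combined cross-platform log2-ratio matrix
#'
#' One row per protein quantified on either platform, one column per
#' (platform, condition): `TMT:<condition>` columns carry the pooled
#' platform's log2 ratios, `LF:<condition>` the label-free log2 fold changes.
#' Proteins missing a value carry `NA`. Column order is deterministic:
#' platform (TMT, LF) by sorted condition name.
#'
#' @param tmt differential table from [run_tmt()].
#' @param lf differential table from [run_labelfree()].
#' @return numeric matrix with proteins as rows.
#' @export
combined_ratio_matrix <- function(tmt, lf) {
  conds <- sort(unique(c(tmt$condition, lf$condition)))
  ids <- sort(unique(c(tmt$protein_id, lf$protein_id)))
  cols <- c(paste0("TMT:", conds), paste0("LF:", conds))
  out <- matrix(NA_real_, length(ids), length(cols), dimnames = list(ids, cols))
  out[cbind(match(tmt$protein_id, ids),
            match(paste0("TMT:", tmt$condition), cols))] <- tmt$log2fc
  out[cbind(match(lf$protein_id, ids),
            match(paste0("LF:", lf$condition), cols))] <- log2(lf$fc)
  out
}

#' Unsupervised hierarchical clustering of condition columns
#'
#' Mirrors the usual heat-map workflow: rows (proteins) with any gap are
#' dropped, remaining rows are z-score normalized (subtract the row mean,
#' divide by the row SD; zero-spread rows are dropped), and the columns are
#' clustered agglomeratively on Euclidean distance with average linkage.
#' Columns are taken in label order, which fixes the tie-break
#' deterministically.
#'
#' @param mat matrix from [combined_ratio_matrix()] (or any proteins x
#'   conditions ratio matrix).
#' @param method agglomeration method for [stats::hclust()].
#' @return an `hclust` object over the columns.
#' @export
cluster_conditions <- function(mat, method = "average") {
  if (!is.matrix(mat) || ncol(mat) < 2)
    input_error("need a matrix with >= 2 columns")
  mat <- mat[, order(colnames(mat) %||% seq_len(ncol(mat))), drop = FALSE]
  complete <- mat[stats::complete.cases(mat), , drop = FALSE]
  sds <- apply(complete, 1, stats::sd)
  complete <- complete[is.finite(sds) & sds > 0, , drop = FALSE]
  if (nrow(complete) < 2)
    input_error("fewer than 2 complete rows available for clustering")
  z <- t(scale(t(complete)))
  stats::hclust(stats::dist(t(z), method = "euclidean"), method = method)
}

#' Export a dendrogram as Newick text
#'
#' @param hc an `hclust` object, e.g. from [cluster_conditions()].
#' @param path optional file; when `NULL` the Newick string is returned.
#' @return Newick string (invisibly when written to file).
#' @export
dendrogram_newick <- function(hc, path = NULL) {
  phy <- ape::as.phylo(hc)
  if (is.null(path)) return(ape::write.tree(phy))
  ape::write.tree(phy, file = path)
  invisible(ape::write.tree(phy))
}

#' Relative-frequency histogram of log2 ratios
#'
#' Bins are centred on integer multiples of `bin_width` (so a symmetric null
#' distribution has its mode bin centred at zero) and cover the data range;
#' relative frequencies sum to one.
#'
#' @param log2_ratios numeric vector.
#' @param bin_width bin width in log2 units.
#' @return data frame `center`, `count`, `freq`.
#' @export
ratio_histogram <- function(log2_ratios, bin_width = 0.1) {
  x <- log2_ratios[is.finite(log2_ratios)]
  if (!length(x)) input_error("no finite ratios to bin")
  if (!(is.numeric(bin_width) && length(bin_width) == 1L && bin_width > 0))
    config_error("bin_width", "must be a single number > 0")
  lo <- round(min(x) / bin_width)
  hi <- round(max(x) / bin_width)
  breaks <- (seq(lo, hi + 1) - 0.5) * bin_width
  h <- graphics::hist(x, breaks = breaks, plot = FALSE, right = FALSE)
  data.frame(center = h$mids, count = h$counts, freq = h$counts / length(x))
}
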