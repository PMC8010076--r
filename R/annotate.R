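#' Map mouse accessions to human orthologs
#'
#' Every input accession ends up in exactly one of: `mapped` (with all its
#' human pairs emitted), `unmapped`, or — additionally flagged — `ambiguous`
#' (mapped to more than one human accession).
#'
#' @param accessions mouse accessions to map.
#' @param map data frame with columns `mouse_acc`, `human_acc` (duplicate
#'   identical rows are collapsed).
#' @return list with `pairs` (data frame `mouse_acc`, `human_acc`),
#'   `unmapped` (character) and `ambiguous` (character, subset of mapped).
#' @export
map_orthologs <- function(accessions, map) {
  if (!all(c("mouse_acc", "human_acc") %in% names(map)))
    input_error("ortholog map needs columns mouse_acc and human_acc")
  map <- unique(map[, c("mouse_acc", "human_acc")])
  accessions <- unique(accessions)
  pairs <- map[map$mouse_acc %in% accessions, , drop = FALSE]
  pairs <- pairs[order(pairs$mouse_acc, pairs$human_acc), , drop = FALSE]
  rownames(pairs) <- NULL
  counts <- table(pairs$mouse_acc)
  list(pairs = pairs,
       unmapped = setdiff(accessions, pairs$mouse_acc),
       ambiguous = names(counts)[counts > 1])
}

#' Look up body-fluid presence flags
#'
#' @param human_accessions accessions to look up.
#' @param presence data frame `human_acc`, `in_csf`, `in_plasma`.
#' @return data frame `human_acc`, `in_csf`, `in_plasma`, `in_db`; accessions
#'   absent from the table get `FALSE`/`FALSE` with `in_db = FALSE`, and the
#'   number of absentees is in attribute `"n_absent"`.
#' @export
presence_lookup <- function(human_accessions, presence) {
  if (!all(c("human_acc", "in_csf", "in_plasma") %in% names(presence)))
    input_error("presence table needs columns human_acc, in_csf, in_plasma")
  acc <- unique(human_accessions)
  idx <- match(acc, presence$human_acc)
  found <- !is.na(idx)
  out <- data.frame(human_acc = acc,
                    in_csf = ifelse(found, presence$in_csf[idx], FALSE),
                    in_plasma = ifelse(found, presence$in_plasma[idx], FALSE),
                    in_db = found,
                    stringsAsFactors = FALSE)
  attr(out, "n_absent") <- sum(!found)
  out
}

#' Venn region counts for two or three sets
#'
#' @param sets named list of 2 or 3 character vectors.
#' @return named integer vector over the `2^k - 1` nonempty regions; region
#'   names join the member set names with `&` and exclusive regions get an
#'   `_only` suffix. Counts partition the union.
#' @export
#' @examples
#' venn_counts(list(A = c("1", "2", "3"), B = c("2", "3", "4"), C = "3"))
venn_counts <- function(sets) {
  if (!is.list(sets) || length(sets) < 2 || length(sets) > 3)
    input_error("venn_counts supports 2 or 3 sets")
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    input_error("sets must be named")
  sets <- lapply(sets, unique)
  universe <- unique(unlist(sets))
  member <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
  if (length(universe) == 1L) member <- matrix(member, nrow = 1)
  k <- length(sets)
  out <- integer(0)
  for (size in seq_len(k)) {
    for (combo in utils::combn(seq_len(k), size, simplify = FALSE)) {
      inside <- rowSums(member[, combo, drop = FALSE]) == size &
        rowSums(member[, -combo, drop = FALSE]) == 0
      nm <- paste(names(sets)[combo], collapse = "&")
      if (size == 1) nm <- paste0(nm, "_only")
      out[nm] <- sum(inside)
    }
  }
  out
}

#' Read a gene-set collection in GMT format
#'
#' GMT: one set per line, tab-separated `set_id`, `description`, members.
#'
#' @param path GMT file path.
#' @return named list of character member vectors; descriptions in attribute
#'   `"description"`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) < 3
  if (any(bad)) input_error("malformed GMT line %d (need id, description, members)",
                            which(bad)[1])
  sets <- lapply(parts, function(x) unique(x[-(1:2)]))
  names(sets) <- vapply(parts, `[[`, character(1), 1)
  attr(sets, "description") <- stats::setNames(
    vapply(parts, `[[`, character(1), 2), names(sets))
  sets
}

#' Hypergeometric overrepresentation test
#'
#' For each gene set, the upper-tail hypergeometric probability of observing
#' at least the seen overlap between the regulated list and the set, given
#' the quantified universe; q-values by BH across sets. Each set is
#' intersected with the universe before testing.
#'
#' @param regulated character vector of regulated accessions; must be a
#'   subset of `universe`.
#' @param universe character vector of quantifiable accessions (the test
#'   background).
#' @param sets named list of gene sets (e.g. from [read_gmt()]).
#' @return data frame `set_id`, `n_set`, `overlap`, `p`, `q`, sorted by `p`.
#' @export
ora_test <- function(regulated, universe, sets) {
  universe <- unique(universe)
  regulated <- unique(regulated)
  if (length(setdiff(regulated, universe)))
    input_error("regulated list contains accessions outside the universe")
  if (!is.list(sets) || is.null(names(sets)))
    input_error("sets must be a named list")
  N <- length(universe)
  n_reg <- length(regulated)
  res <- lapply(names(sets), function(id) {
    s <- intersect(unique(sets[[id]]), universe)
    k <- length(intersect(regulated, s))
    p <- stats::phyper(k - 1, length(s), N - length(s), n_reg, lower.tail = FALSE)
    data.frame(set_id = id, n_set = length(s), overlap = k, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q <- bh_adjust(out$p)
  out <- out[order(out$p, out$set_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
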