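# End-to-end orchestration: parse a config, simulate or read the two
# quantification matrices, run both pipelines, integrate, annotate, write
# every stage's table as commented TSV, and benchmark against truth when the
# inputs are simulated.

#' Read a reporter or abundance matrix from TSV
#'
#' Expects a header row and a first column of accessions; remaining columns
#' numeric. Empty cells and `NA` become missing values.
#'
#' @param path TSV path.
#' @return numeric matrix with accession rownames.
#' @export
read_quant_matrix <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2) input_error("quantification table needs an id column plus data")
  if (anyDuplicated(df[[1]])) input_error("duplicated accession in %s", path)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df[[1]]
  m
}

parse_pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) config_error("config", "file not found: %s", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) config_error("config", "must be a list or a YAML file path")
  config
}

design_from_config <- function(cfg) {
  if (is.null(cfg$design)) return(default_study_design())
  d <- cfg$design
  base <- default_study_design()
  thr_cfg <- d$thresholds %||% list()
  q_max <- unlist(thr_cfg$q_max %||% as.list(base$thresholds$q_max))
  control_map <- unlist(d$control_map %||% as.list(base$control_map))
  unknown_q <- setdiff(names(q_max), names(control_map))
  if (length(unknown_q))
    config_error("design$thresholds$q_max", "unknown condition: %s",
                 paste(unknown_q, collapse = ", "))
  thresholds <- cascade_thresholds(
    fc_up = thr_cfg$fc_up %||% base$thresholds$fc_up,
    fc_down = thr_cfg$fc_down %||% base$thresholds$fc_down,
    p_max = thr_cfg$p_max %||% base$thresholds$p_max,
    q_max = q_max
  )
  study_design(
    control_map = control_map,
    channels = unlist(d$channels %||% as.list(base$channels)),
    group_sizes = unlist(d$group_sizes %||% as.list(base$group_sizes)),
    thresholds = thresholds,
    tmt_q_cut = d$tmt_q_cut %||% base$tmt_q_cut
  )
}

#' Run the full pipeline from a configuration
#'
#' Orchestrates simulate (or load) -> pooled pipeline -> label-free pipeline
#' -> integration -> annotation, writing every stage's output as TSV with a
#' commented provenance header (config fingerprint, seed, row counts), plus a
#' benchmark report when ground truth is available. Deterministic under a
#' fixed seed; all validation happens before any stage runs.
#'
#' The configuration is a named list (or YAML file) with optional entries:
#' `simulate` (arguments for [sim_config()]; omit to read files instead),
#' `inputs` (`reporter`, `abundance`, `samples`, `orthologs`, `presence`,
#' `gene_sets` file paths), `design` (overrides of [default_study_design()]:
#' `control_map`, `channels`, `group_sizes`, `tmt_q_cut`, `thresholds`), and
#' `seed`.
#'
#' @param config list or YAML path, see Details.
#' @param out_dir output directory (created if needed).
#' @param seed overrides `config$seed`.
#' @param quiet suppress per-stage log messages.
#' @return invisibly, a list with the `dualquant` fit, the benchmark (or
#'   `NULL`), and the written file paths.
#' @export
#' @examples
#' out <- run_pipeline(list(simulate = list(n_proteins = 200), seed = 5),
#'                     out_dir = tempfile(), quiet = TRUE)
#' names(out$files)
run_pipeline <- function(config = list(), out_dir = ".", seed = NULL,
                         quiet = FALSE) {
  cfg <- parse_pipeline_config(config)
  seed <- as.integer(seed %||% cfg$seed %||% 1L)
  design <- design_from_config(cfg)
  hash <- config_hash(list(cfg, seed))
  say <- function(fmt, ...) if (!quiet) message(sprintf(fmt, ...))
  meta <- function(stage, n) list(stage = stage, rows = n, seed = seed,
                                  config_hash = hash)

  truth <- NULL
  orthologs <- NULL
  presence <- NULL
  gene_sets <- NULL
  if (!is.null(cfg$simulate)) {
    sim_args <- cfg$simulate
    sim_args$seed <- seed
    sim_args$design <- design
    scfg <- do.call(sim_config, sim_args)
    study <- simulate_study(scfg)
    truth <- study$truth
    reporter <- study$reporter
    values <- study$labelfree$values
    samples <- study$labelfree$samples
    orthologs <- study$orthologs
    presence <- study$presence
    say("simulate: %d proteins, %d regulated", scfg$n_proteins,
        sum(rowSums(truth$effects != 0) > 0))
  } else {
    inp <- cfg$inputs %||% config_error("inputs", "either 'simulate' or 'inputs' is required")
    reporter <- read_quant_matrix(inp$reporter %||%
                                    config_error("inputs$reporter", "is required"))
    values <- read_quant_matrix(inp$abundance %||%
                                  config_error("inputs$abundance", "is required"))
    samples <- utils::read.delim(inp$samples %||%
                                   config_error("inputs$samples", "is required"),
                                 comment.char = "#", stringsAsFactors = FALSE)
    if (!is.null(inp$orthologs)) orthologs <- read_dq_tsv(inp$orthologs)
    if (!is.null(inp$presence)) {
      presence <- read_dq_tsv(inp$presence)
      for (cl in c("in_csf", "in_plasma"))
        presence[[cl]] <- presence[[cl]] %in% c("Y", "TRUE", "yes", TRUE)
    }
  }
  if (!is.null(cfg$inputs$gene_sets)) gene_sets <- read_gmt(cfg$inputs$gene_sets)

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- list()
  put <- function(name, df, stage) {
    path <- file.path(out_dir, name)
    write_dq_tsv(df, path, meta(stage, nrow(df)))
    say("%s: wrote %d rows to %s", stage, nrow(df), name)
    files[[name]] <<- path
  }

  fit <- dualquant(reporter, values, samples, design)

  if (!is.null(truth)) {
    put("truth.tsv", cbind(truth$proteins,
                           stats::setNames(as.data.frame(truth$effects),
                                           paste0("effect.", colnames(truth$effects)))),
        "simulate")
    put("reporter_matrix.tsv",
        data.frame(protein_id = rownames(reporter), reporter,
                   check.names = FALSE), "simulate")
    put("abundance_matrix.tsv",
        data.frame(protein_id = rownames(values), values, check.names = FALSE),
        "simulate")
    put("sample_sheet.tsv", samples, "simulate")
  }
  put("tmt_differential.tsv", fit$tmt, "run-tmt")
  put("labelfree_differential.tsv", fit$labelfree, "run-labelfree")
  put("overlap_counts.tsv",
      data.frame(region = names(fit$overlap$counts),
                 count = as.integer(fit$overlap$counts)), "integrate")

  verified <- fit$verified
  if (!is.null(orthologs)) {
    mapping <- map_orthologs(unique(verified$protein_id), orthologs)
    if (!is.null(presence)) {
      flags <- presence_lookup(mapping$pairs$human_acc, presence)
      merged <- merge(mapping$pairs, flags, by = "human_acc")
      verified$in_csf <- FALSE
      verified$in_plasma <- FALSE
      if (nrow(merged)) {
        # one-to-many orthologs: OR the human-side flags back onto the mouse accession
        agg <- stats::aggregate(cbind(in_csf, in_plasma) ~ mouse_acc, merged, any)
        idx <- match(verified$protein_id, agg$mouse_acc)
        verified$in_csf <- !is.na(idx) & agg$in_csf[pmax(idx, 1L)]
        verified$in_plasma <- !is.na(idx) & agg$in_plasma[pmax(idx, 1L)]
      }
      verified$ambiguous_ortholog <- verified$protein_id %in% mapping$ambiguous
    }
  }
  put("verified_proteins.tsv", verified, "integrate")
  put("evidence_weights.tsv",
      fit$weights[!is.na(fit$weights$weight), , drop = FALSE], "integrate")

  hist_tab <- do.call(rbind, lapply(design$disease, function(cond) {
    h <- ratio_histogram(fit$tmt$log2fc[fit$tmt$condition == cond])
    cbind(condition = cond, platform = "TMT", h)
  }))
  put("ratio_histograms.tsv", hist_tab, "integrate")

  if (!is.null(fit$clustering)) {
    nwk_path <- file.path(out_dir, "condition_dendrogram.nwk")
    writeLines(dendrogram_newick(fit$clustering), nwk_path)
    files[["condition_dendrogram.nwk"]] <- nwk_path
    say("integrate: wrote condition dendrogram")
  }

  if (!is.null(gene_sets)) {
    universe <- unique(c(rownames(reporter), rownames(values)))
    enr <- ora_test(unique(verified$protein_id), universe, gene_sets)
    put("enrichment.tsv", enr, "enrich")
  }

  benchmark <- NULL
  if (!is.null(truth)) {
    benchmark <- score_against_truth(fit, truth)
    put("benchmark.tsv",
        data.frame(metric = c("sensitivity", "fdp", "direction_accuracy",
                              "n_true", "n_called", "n_correct"),
                   value = c(benchmark$sensitivity, benchmark$fdp,
                             benchmark$direction_accuracy, benchmark$n_true,
                             benchmark$n_called, benchmark$n_correct)),
        "report")
  }
  say("done: %d verified records", nrow(verified))
  invisible(list(fit = fit, benchmark = benchmark, truth = truth,
                 files = files, config_hash = hash))
}
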