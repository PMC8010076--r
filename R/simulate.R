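#' Simulation configuration
#'
#' Collects every knob of the synthetic study generator. Defaults emulate the
#' frontal-cortex study the package models: ~2000 quantified proteins, 5% of
#' them truly regulated with |log2 fold change| between 1 and 2.5,
#' between-animal biological noise of 0.4 log2 units, technical measurement
#' noise of 0.1 log2 units, small fixed per-channel loading offsets, and 5%
#' values missing completely at random in the per-animal matrix (the pooled
#' reporter matrix has no missing values).
#'
#' `scheme` controls how a regulated protein's true effect is structured
#' across disease conditions: `"by_control"` (default) draws one effect per
#' control block, so the two EAE stages share an effect while the cuprizone
#' effect is independent; `"shared"` uses a single effect everywhere;
#' `"independent"` draws an effect per condition. `sign_mode` controls effect
#' directions: `"iid"` (default) draws a random sign per block;
#' `"median_neutral"` ties the sign to the protein's side of the abundance
#' median (up-spikes above it, down-spikes below), which guarantees spiked
#' regulation cannot shift any channel median, keeping median-based
#' normalization exactly unbiased — the property a spike-in benchmark needs if
#' measured ratios are to reproduce the encoded truth exactly in the
#' noise-free limit.
#'
#' @param n_proteins number of simulated proteins.
#' @param frac_regulated fraction of proteins with a true effect, in \[0, 1\].
#' @param effect_range_log2 length-2 range of |log2 fold change| magnitudes.
#' @param group_sizes named vector of animals per condition; defaults come
#'   from `design`.
#' @param channel_offsets named numeric vector (condition -> log2 loading
#'   offset of its reporter channel).
#' @param noise_sd_within between-animal biological SD (log2 units).
#' @param noise_sd_tech technical measurement SD (log2 units).
#' @param run_offset_sd SD of per-run log2 loading offsets in the label-free
#'   matrix (removed by run normalization).
#' @param missing_rate MCAR missingness rate of the per-animal matrix, in \[0, 1).
#' @param base_log2_mean,base_log2_sd log2-normal protein abundance parameters.
#' @param scheme effect structure across conditions, see Details.
#' @param sign_mode effect sign assignment, see Details.
#' @param pooling how pooled channels aggregate individuals: `"log"`
#'   (arithmetic mean of log2 abundances, default) or `"linear"`.
#' @param seed integer seed; every generator call derives its stream from it.
#' @param design the `dq_design` the simulation must match.
#' @return an object of class `dq_sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(n_proteins = 500, seed = 7)
#' cfg$group_sizes
sim_config <- function(n_proteins = 2000,
                       frac_regulated = 0.05,
                       effect_range_log2 = c(1, 2.5),
                       group_sizes = NULL,
                       channel_offsets = c("CPZ-42d" = 0.2, "CTR-EAE" = 0.05,
                                           "EAE-16d" = -0.1, "EAE-32d" = 0.15,
                                           "CTR-CPZ" = -0.2),
                       noise_sd_within = 0.4,
                       noise_sd_tech = 0.1,
                       run_offset_sd = 0.3,
                       missing_rate = 0.05,
                       base_log2_mean = 20,
                       base_log2_sd = 1.5,
                       scheme = c("by_control", "shared", "independent"),
                       sign_mode = c("iid", "median_neutral"),
                       pooling = c("log", "linear"),
                       seed = 1L,
                       design = default_study_design()) {
  scheme <- match.arg(scheme)
  sign_mode <- match.arg(sign_mode)
  pooling <- match.arg(pooling)
  if (!is_count(n_proteins)) config_error("n_proteins", "must be a positive integer")
  if (!is_prob(frac_regulated)) config_error("frac_regulated", "must be in [0, 1]")
  if (!(is.numeric(effect_range_log2) && length(effect_range_log2) == 2L &&
        all(is.finite(effect_range_log2)) &&
        effect_range_log2[1] <= effect_range_log2[2]))
    config_error("effect_range_log2", "must be a finite non-decreasing length-2 range")
  if (frac_regulated > 0 && effect_range_log2[1] <= 0)
    config_error("effect_range_log2", "magnitudes must be > 0 when regulation is requested")
  if (is.null(group_sizes)) group_sizes <- design$group_sizes
  miss_n <- setdiff(design$conditions, names(group_sizes))
  if (length(miss_n))
    config_error("group_sizes", "missing condition(s): %s", paste(miss_n, collapse = ", "))
  group_sizes <- group_sizes[design$conditions]
  if (any(group_sizes < 2 | group_sizes != round(group_sizes)))
    config_error("group_sizes", "all groups must have >= 2 animals")
  miss_c <- setdiff(design$conditions, names(channel_offsets))
  if (length(miss_c))
    config_error("channel_offsets", "missing condition(s): %s", paste(miss_c, collapse = ", "))
  channel_offsets <- channel_offsets[design$conditions]
  if (any(!is.finite(channel_offsets)))
    config_error("channel_offsets", "offsets must be finite")
  if (!(is.numeric(noise_sd_within) && length(noise_sd_within) == 1L && noise_sd_within >= 0))
    config_error("noise_sd_within", "must be a single number >= 0")
  if (!(is.numeric(noise_sd_tech) && length(noise_sd_tech) == 1L && noise_sd_tech >= 0))
    config_error("noise_sd_tech", "must be a single number >= 0")
  if (!(is.numeric(run_offset_sd) && length(run_offset_sd) == 1L && run_offset_sd >= 0))
    config_error("run_offset_sd", "must be a single number >= 0")
  if (!is_prob(missing_rate, open_right = TRUE))
    config_error("missing_rate", "must be in [0, 1)")
  if (!(is.numeric(base_log2_sd) && base_log2_sd > 0))
    config_error("base_log2_sd", "must be > 0")
  if (!is_count(abs(seed) + 1)) config_error("seed", "must be an integer")
  structure(list(
    n_proteins = as.integer(n_proteins),
    frac_regulated = frac_regulated,
    effect_range_log2 = effect_range_log2,
    group_sizes = stats::setNames(as.integer(group_sizes), design$conditions),
    channel_offsets = channel_offsets,
    noise_sd_within = noise_sd_within,
    noise_sd_tech = noise_sd_tech,
    run_offset_sd = run_offset_sd,
    missing_rate = missing_rate,
    base_log2_mean = base_log2_mean,
    base_log2_sd = base_log2_sd,
    scheme = scheme,
    sign_mode = sign_mode,
    pooling = pooling,
    seed = as.integer(seed),
    design = design
  ), class = "dq_sim_config")
}

# Blocks of disease conditions that share one true effect under the config scheme.
effect_blocks <- function(config) {
  design <- config$design
  switch(config$scheme,
    shared      = list(all = design$disease),
    by_control  = split(design$disease, design$control_map[design$disease]),
    independent = stats::setNames(as.list(design$disease), design$disease)
  )
}

#' Generate the ground-truth table of a simulated study
#'
#' Draws a base log2 abundance per protein and spikes
#' `round(n_proteins * frac_regulated)` proteins with a nonzero log2 effect in
#' every disease condition; effect magnitudes are uniform on
#' `effect_range_log2` and structured across conditions according to
#' `config$scheme` / `config$sign_mode` (see [sim_config()]).
#'
#' @param config a [sim_config()] object.
#' @return an object of class `dq_truth`: list with `proteins` (data frame of
#'   `protein_id`, `base_log2_abundance`, `regulated`) and `effects` (proteins
#'   x disease-conditions matrix of true log2 fold changes, 0 = unregulated).
#' @export
#' @examples
#' tr <- generate_truth(sim_config(n_proteins = 100, frac_regulated = 0.1, seed = 1))
#' sum(rowSums(tr$effects != 0) > 0)  # exactly 10
generate_truth <- function(config) {
  if (!inherits(config, "dq_sim_config"))
    config_error("config", "must be built with sim_config()")
  design <- config$design
  set.seed(config$seed)
  n <- config$n_proteins
  ids <- sprintf("SIMP%05d", seq_len(n))
  base <- stats::rnorm(n, config$base_log2_mean, config$base_log2_sd)
  effects <- matrix(0, n, length(design$disease),
                    dimnames = list(ids, design$disease))
  n_reg <- round(n * config$frac_regulated)
  reg <- sort(sample.int(n, n_reg))
  if (n_reg > 0) {
    blocks <- effect_blocks(config)
    for (bl in blocks) {
      mag <- stats::runif(n_reg, config$effect_range_log2[1], config$effect_range_log2[2])
      sgn <- switch(config$sign_mode,
        iid = sample(c(-1, 1), n_reg, replace = TRUE),
        median_neutral = ifelse(base[reg] > stats::median(base), 1, -1)
      )
      effects[reg, bl] <- mag * sgn
    }
  }
  structure(list(
    proteins = data.frame(protein_id = ids,
                          base_log2_abundance = base,
                          regulated = seq_len(n) %in% reg,
                          stringsAsFactors = FALSE),
    effects = effects
  ), class = "dq_truth")
}

#' Simulate a pooled reporter-intensity matrix
#'
#' Emulates an isobaric-label experiment in which equal protein amounts from
#' each animal of a condition are pooled into one labelled channel: for every
#' condition, per-animal log2 abundances (base + effect + between-animal
#' noise) are drawn, aggregated (arithmetic mean on the log2 scale by default,
#' linear-scale mean via `config$pooling`), shifted by the channel's loading
#' offset, perturbed by technical noise, and returned on the linear intensity
#' scale. The pooled design has no missing values.
#'
#' @param truth a [generate_truth()] result.
#' @param config the matching [sim_config()].
#' @return numeric matrix, proteins x conditions, linear-scale intensities;
#'   attribute `"channels"` carries the condition -> reporter-channel map.
#' @export
simulate_tmt <- function(truth, config) {
  if (!inherits(truth, "dq_truth")) input_error("truth must come from generate_truth()")
  if (!inherits(config, "dq_sim_config"))
    config_error("config", "must be built with sim_config()")
  design <- config$design
  miss <- setdiff(design$conditions, names(config$channel_offsets))
  if (length(miss))
    design_error("condition without a channel offset: %s", paste(miss, collapse = ", "))
  set.seed(config$seed + 1L)
  n <- nrow(truth$proteins)
  out <- matrix(NA_real_, n, length(design$conditions),
                dimnames = list(truth$proteins$protein_id, design$conditions))
  for (cond in design$conditions) {
    eff <- if (cond %in% design$disease) truth$effects[, cond] else 0
    n_g <- config$group_sizes[[cond]]
    indiv <- truth$proteins$base_log2_abundance + eff +
      matrix(stats::rnorm(n * n_g, 0, config$noise_sd_within), n, n_g)
    pooled <- if (config$pooling == "log") rowMeans(indiv) else log2(rowMeans(2^indiv))
    out[, cond] <- 2^(pooled + config$channel_offsets[[cond]] +
                        stats::rnorm(n, 0, config$noise_sd_tech))
  }
  attr(out, "channels") <- design$channels
  out
}

#' Simulate a per-animal label-free abundance matrix
#'
#' One column per animal: log2 abundance = base + condition effect +
#' between-animal noise + technical noise + a per-run loading offset, returned
#' on the linear scale with values masked missing completely at random at
#' `config$missing_rate`.
#'
#' @inheritParams simulate_tmt
#' @return list with `values` (proteins x samples linear matrix, `NA` =
#'   missing) and `samples` (data frame `sample_id`, `condition`).
#' @export
simulate_labelfree <- function(truth, config) {
  if (!inherits(truth, "dq_truth")) input_error("truth must come from generate_truth()")
  if (!inherits(config, "dq_sim_config"))
    config_error("config", "must be built with sim_config()")
  design <- config$design
  set.seed(config$seed + 2L)
  n <- nrow(truth$proteins)
  cols <- list()
  sample_id <- character(0)
  condition <- character(0)
  for (cond in design$conditions) {
    eff <- if (cond %in% design$disease) truth$effects[, cond] else 0
    n_g <- config$group_sizes[[cond]]
    run_off <- stats::rnorm(n_g, 0, config$run_offset_sd)
    for (a in seq_len(n_g)) {
      lg <- truth$proteins$base_log2_abundance + eff +
        stats::rnorm(n, 0, config$noise_sd_within) +
        stats::rnorm(n, 0, config$noise_sd_tech) + run_off[a]
      cols[[length(cols) + 1L]] <- 2^lg
      sample_id <- c(sample_id, sprintf("%s_%02d", cond, a))
      condition <- c(condition, cond)
    }
  }
  values <- do.call(cbind, cols)
  dimnames(values) <- list(truth$proteins$protein_id, sample_id)
  if (config$missing_rate > 0) {
    values[stats::runif(length(values)) < config$missing_rate] <- NA_real_
  }
  list(values = values,
       samples = data.frame(sample_id = sample_id, condition = condition,
                            stringsAsFactors = FALSE))
}

#' Generate a synthetic mouse-to-human ortholog map
#'
#' @param protein_ids mouse accessions to map.
#' @param frac_mapped fraction of accessions receiving at least one human
#'   ortholog.
#' @param frac_one_to_many fraction of mapped accessions receiving two human
#'   orthologs (the ambiguity real ortholog resources exhibit).
#' @param seed integer seed.
#' @return data frame with columns `mouse_acc`, `human_acc`.
#' @export
make_ortholog_map <- function(protein_ids, frac_mapped = 0.9,
                              frac_one_to_many = 0.05, seed = 1L) {
  if (!is_prob(frac_mapped)) config_error("frac_mapped", "must be in [0, 1]")
  if (!is_prob(frac_one_to_many)) config_error("frac_one_to_many", "must be in [0, 1]")
  set.seed(seed)
  n_map <- round(length(protein_ids) * frac_mapped)
  if (n_map == 0)
    return(data.frame(mouse_acc = character(0), human_acc = character(0),
                      stringsAsFactors = FALSE))
  mapped <- sort(sample(protein_ids, n_map))
  human <- sprintf("HS%05d", seq_len(n_map))
  out <- data.frame(mouse_acc = mapped, human_acc = human, stringsAsFactors = FALSE)
  n_multi <- round(n_map * frac_one_to_many)
  if (n_multi > 0) {
    multi <- sample(mapped, n_multi)
    out <- rbind(out, data.frame(
      mouse_acc = multi,
      human_acc = sprintf("HS%05d", n_map + seq_len(n_multi)),
      stringsAsFactors = FALSE))
  }
  out[order(out$mouse_acc, out$human_acc), , drop = FALSE]
}

#' Generate a synthetic body-fluid presence table
#'
#' Emulates a CSF/plasma proteome resource as two independent Bernoulli flags
#' per human accession.
#'
#' @param human_accessions accessions to flag.
#' @param frac_csf marginal probability of CSF detection.
#' @param frac_plasma marginal probability of plasma detection.
#' @param seed integer seed.
#' @return data frame with columns `human_acc`, `in_csf`, `in_plasma` (logical).
#' @export
make_presence_db <- function(human_accessions, frac_csf = 0.5,
                             frac_plasma = 0.4, seed = 1L) {
  if (!is_prob(frac_csf)) config_error("frac_csf", "must be in [0, 1]")
  if (!is_prob(frac_plasma)) config_error("frac_plasma", "must be in [0, 1]")
  set.seed(seed)
  acc <- unique(human_accessions)
  data.frame(human_acc = acc,
             in_csf = stats::runif(length(acc)) < frac_csf,
             in_plasma = stats::runif(length(acc)) < frac_plasma,
             stringsAsFactors = FALSE)
}

#' Simulate a complete two-platform study
#'
#' Convenience wrapper: truth table, pooled reporter matrix, per-animal
#' abundance matrix, ortholog map and body-fluid presence table, all from one
#' configuration. Deterministic given `config$seed`.
#'
#' @param config a [sim_config()] object.
#' @param frac_mapped,frac_one_to_many,frac_csf,frac_plasma annotation-table
#'   parameters, see [make_ortholog_map()] and [make_presence_db()].
#' @return list with elements `truth`, `reporter`, `labelfree`, `orthologs`,
#'   `presence`, `config`.
#' @export
#' @examples
#' study <- simulate_study(sim_config(n_proteins = 200, seed = 3))
#' dim(study$reporter)
simulate_study <- function(config, frac_mapped = 0.9, frac_one_to_many = 0.05,
                           frac_csf = 0.5, frac_plasma = 0.4) {
  truth <- generate_truth(config)
  reporter <- simulate_tmt(truth, config)
  labelfree <- simulate_labelfree(truth, config)
  orthologs <- make_ortholog_map(truth$proteins$protein_id, frac_mapped,
                                 frac_one_to_many, seed = config$seed + 3L)
  presence <- make_presence_db(orthologs$human_acc, frac_csf, frac_plasma,
                               seed = config$seed + 4L)
  list(truth = truth, reporter = reporter, labelfree = labelfree,
       orthologs = orthologs, presence = presence, config = config)
}
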