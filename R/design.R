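#' Significance cascade thresholds for the label-free platform
#'
#' A protein is called regulated on the label-free platform only when its fold
#' change over the pooled control clears the dead band (`>= fc_up` or
#' `<= fc_down`), its ANOVA p-value is below `p_max`, and its BH q-value is
#' below the condition-specific cut-off `q_max[condition]`. The per-condition
#' q cut-offs reflect how consistently the animals of a condition respond: a
#' condition with uniform regulation across individuals supports a stringent
#' cut-off, a heterogeneous recovery-phase condition a looser one.
#'
#' @param fc_up upper fold-change bound (linear scale, default 2.0).
#' @param fc_down lower fold-change bound (linear scale, default 0.7).
#' @param p_max maximum ANOVA p-value (default 0.05).
#' @param q_max named numeric vector of per-condition q cut-offs.
#' @return an object of class `dq_thresholds`.
#' @export
#' @examples
#' cascade_thresholds()
cascade_thresholds <- function(fc_up = 2.0, fc_down = 0.7, p_max = 0.05,
                               q_max = c("CPZ-42d" = 0.05,
                                         "EAE-16d" = 0.051,
                                         "EAE-32d" = 0.11)) {
  if (!(is.numeric(fc_up) && length(fc_up) == 1L && fc_up > 1))
    config_error("fc_up", "must be a single number > 1")
  if (!(is.numeric(fc_down) && length(fc_down) == 1L && fc_down > 0 && fc_down < 1))
    config_error("fc_down", "must be a single number in (0, 1)")
  if (!is_prob(p_max) || p_max <= 0 || p_max >= 1)
    config_error("p_max", "must be in (0, 1)")
  if (!is.numeric(q_max) || is.null(names(q_max)) || any(!nzchar(names(q_max))))
    config_error("q_max", "must be a named numeric vector (condition -> q cut-off)")
  if (any(q_max <= 0 | q_max >= 1))
    config_error("q_max", "all cut-offs must be in (0, 1)")
  structure(list(fc_up = fc_up, fc_down = fc_down, p_max = p_max,
                 q_max = q_max),
            class = "dq_thresholds")
}

#' Construct a study design
#'
#' Describes the conditions of a two-platform study: which conditions are
#' disease vs control, which control each disease condition is ratioed
#' against, which isobaric reporter channel carries each condition in the
#' pooled experiment, and how many animals each group contains in the
#' per-animal experiment.
#'
#' @param control_map named character vector: disease condition -> its control
#'   condition.
#' @param channels named character vector: condition -> reporter channel label.
#'   Every condition (disease and control) must have a unique channel.
#' @param group_sizes named integer vector: condition -> number of animals.
#' @param thresholds label-free significance cascade, see
#'   [cascade_thresholds()]; its `q_max` must cover every disease condition.
#' @param tmt_q_cut BH q cut-off for the pooled-platform regulation call
#'   (default 0.05).
#' @return an object of class `dq_design`.
#' @seealso [default_study_design()] for the mouse multiple-sclerosis-model
#'   frontal-cortex design this package was built around.
#' @export
study_design <- function(control_map, channels, group_sizes,
                         thresholds = cascade_thresholds(),
                         tmt_q_cut = 0.05) {
  if (!is.character(control_map) || is.null(names(control_map)))
    design_error("control_map must be a named character vector (disease -> control)")
  disease <- names(control_map)
  controls <- unique(unname(control_map))
  if (any(disease %in% controls))
    design_error("a condition cannot be both disease and control: %s",
                 paste(intersect(disease, controls), collapse = ", "))
  conditions <- c(disease, controls)
  if (anyDuplicated(disease))
    design_error("duplicated disease condition in control_map")
  if (!is.character(channels) || is.null(names(channels)))
    design_error("channels must be a named character vector (condition -> channel)")
  missing_ch <- setdiff(conditions, names(channels))
  if (length(missing_ch))
    design_error("condition without a reporter channel: %s",
                 paste(missing_ch, collapse = ", "))
  if (anyDuplicated(channels[conditions]))
    design_error("reporter channels must be unique")
  if (!is.numeric(group_sizes) || is.null(names(group_sizes)))
    design_error("group_sizes must be a named numeric vector")
  missing_n <- setdiff(conditions, names(group_sizes))
  if (length(missing_n))
    design_error("condition without a group size: %s", paste(missing_n, collapse = ", "))
  gs <- group_sizes[conditions]
  if (any(gs < 2 | gs != round(gs)))
    design_error("group sizes must be integers >= 2")
  if (!inherits(thresholds, "dq_thresholds"))
    design_error("thresholds must be built with cascade_thresholds()")
  missing_q <- setdiff(disease, names(thresholds$q_max))
  if (length(missing_q))
    design_error("disease condition missing from thresholds q_max: %s",
                 paste(missing_q, collapse = ", "))
  extra_q <- setdiff(names(thresholds$q_max), disease)
  if (length(extra_q))
    design_error("unknown condition in thresholds q_max: %s",
                 paste(extra_q, collapse = ", "))
  if (!is_prob(tmt_q_cut) || tmt_q_cut <= 0 || tmt_q_cut >= 1)
    design_error("tmt_q_cut must be in (0, 1)")
  structure(list(
    conditions = conditions,
    disease = disease,
    controls = controls,
    control_map = control_map,
    channels = channels[conditions],
    group_sizes = stats::setNames(as.integer(gs), conditions),
    thresholds = thresholds,
    tmt_q_cut = tmt_q_cut
  ), class = "dq_design")
}

#' Default study design: cuprizone and EAE mouse cortex
#'
#' The design this package models: two mouse multiple-sclerosis models
#' (cuprizone demyelination sampled at 42 days; MOG-induced EAE sampled at the
#' day-16 disease peak and the day-32 recovery phase) each with a matched
#' control, one reporter channel per condition in the pooled six-plex
#' experiment, and per-animal group sizes 5 (CPZ-42d), 6 (EAE-16d),
#' 12 (EAE-32d), 6 (CTR-CPZ) and 5 (CTR-EAE), so the pooled control used by
#' the label-free comparison has 11 animals.
#'
#' @return a `dq_design` object.
#' @export
#' @examples
#' d <- default_study_design()
#' d$control_map
default_study_design <- function() {
  study_design(
    control_map = c("CPZ-42d" = "CTR-CPZ",
                    "EAE-16d" = "CTR-EAE",
                    "EAE-32d" = "CTR-EAE"),
    channels = c("CPZ-42d" = "TMT126", "CTR-EAE" = "TMT127",
                 "EAE-16d" = "TMT128", "EAE-32d" = "TMT129",
                 "CTR-CPZ" = "TMT130"),
    group_sizes = c("CPZ-42d" = 5, "EAE-16d" = 6, "EAE-32d" = 12,
                    "CTR-CPZ" = 6, "CTR-EAE" = 5)
  )
}

#' @export
print.dq_design <- function(x, ...) {
  cat("Study design (", length(x$disease), " disease, ",
      length(x$controls), " control conditions)\n", sep = "")
  for (d in x$disease) {
    cat(sprintf("  %-10s vs %-10s  channel %s  n=%d  q_max=%g\n",
                d, x$control_map[[d]], x$channels[[d]],
                x$group_sizes[[d]], x$thresholds$q_max[[d]]))
  }
  for (ctl in x$controls) {
    cat(sprintf("  %-10s (control)      channel %s  n=%d\n",
                ctl, x$channels[[ctl]], x$group_sizes[[ctl]]))
  }
  cat(sprintf("  pooled-platform q cut-off: %g\n", x$tmt_q_cut))
  invisible(x)
}
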