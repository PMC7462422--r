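#' Validate and complete a study configuration
#'
#' Checks a raw configuration list, fills defaults, and reports every problem
#' at once rather than stopping at the first.  A configuration names its
#' cohort source (a manifest path or a [cohort_design()]), the conditions,
#' properties and scenarios to analyse, the component grid, the clamping
#' constant, a seed and an output directory.
#'
#' @param config A named list with (a subset of) fields `manifest`, `design`,
#'   `conditions`, `properties`, `scenarios`, `m_range`, `eps_clamp`, `seed`,
#'   `out_dir`.
#' @return A validated `study_config` list with defaults filled in:
#'   `eps_clamp = eps_clamp_default()`, both scenarios, all eight properties,
#'   full component sweep (`m_range = NULL`).
#' @export
validate_config <- function(config) {
  problems <- character()
  cfg <- config
  has_manifest <- !is.null(cfg$manifest)
  has_design <- !is.null(cfg$design)
  if (!has_manifest && !has_design) {
    problems <- c(problems, "config needs a cohort source: `manifest` path or `design`.")
  }
  if (has_manifest && has_design) {
    problems <- c(problems, "give either `manifest` or `design`, not both.")
  }
  if (has_manifest && !file.exists(cfg$manifest)) {
    problems <- c(problems, sprintf("manifest '%s' does not exist.", cfg$manifest))
  }
  if (has_design && !inherits(cfg$design, "cohort_design")) {
    problems <- c(problems, "`design` must be a cohort_design object.")
  }
  cfg$properties <- cfg$properties %||% network_property_names()
  bad <- setdiff(cfg$properties, network_property_names())
  if (length(bad)) {
    problems <- c(problems, sprintf(
      "unknown propert%s %s; supported: %s.",
      if (length(bad) > 1) "ies" else "y",
      paste0("'", bad, "'", collapse = ", "),
      paste(network_property_names(), collapse = ", ")
    ))
  }
  cfg$scenarios <- cfg$scenarios %||% scenario_names()
  bad_sc <- setdiff(cfg$scenarios, scenario_names())
  if (length(bad_sc)) {
    problems <- c(problems, sprintf("unknown scenario(s): %s.",
                                    paste0("'", bad_sc, "'", collapse = ", ")))
  }
  if (!is.null(cfg$conditions) && length(cfg$conditions) == 0) {
    problems <- c(problems, "`conditions` must not be empty.")
  }
  if (!is.null(cfg$m_range)) {
    mr <- cfg$m_range
    if (!is.numeric(mr) || length(mr) == 0 || any(mr < 1) || any(mr != round(mr))) {
      problems <- c(problems, "`m_range` must be positive integers.")
    } else if (length(mr) == 2 && mr[1] > mr[2]) {
      problems <- c(problems, sprintf("`m_range` %d:%d is reversed.", mr[1], mr[2]))
    } else if (length(mr) == 2) {
      cfg$m_range <- seq(mr[1], mr[2])
    }
  }
  cfg$eps_clamp <- cfg$eps_clamp %||% eps_clamp_default()
  if (!is.numeric(cfg$eps_clamp) || cfg$eps_clamp <= 0) {
    problems <- c(problems, "`eps_clamp` must be positive.")
  }
  if (length(problems)) abort(c("Invalid study configuration:", problems))
  structure(cfg, class = "study_config")
}

#' Run a study from a validated configuration
#'
#' Loads (or generates) the cohort named by the configuration, runs
#' [run_study()], and, when `out_dir` is set, writes outputs plus a
#' provenance record with [write_study()].
#'
#' @param config A list accepted by [validate_config()], or a `study_config`.
#' @return The `idiff_study`.
#' @export
run_study_config <- function(config) {
  cfg <- if (inherits(config, "study_config")) config else validate_config(config)
  cohort <- if (!is.null(cfg$manifest)) read_cohort(cfg$manifest) else generate_cohort(cfg$design)
  study <- run_study(cohort,
                     conditions = cfg$conditions,
                     properties = cfg$properties,
                     scenarios = cfg$scenarios,
                     m_range = cfg$m_range,
                     eps_clamp = cfg$eps_clamp)
  if (!is.null(cfg$out_dir)) {
    write_study(study, cfg$out_dir, seed = cfg$seed %||% cfg$design$seed)
  }
  study
}
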