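## The two orders in which the identifiability framework can be applied:
##   NP_of_reconstructed_FC  - reconstruct the connectomes, then derive the
##                             network property from each reconstruction
##   reconstructed_NP_of_FC  - derive the property from the original
##                             (clamped) connectomes, then reconstruct the
##                             property feature matrix itself
## plus the FC_baseline (identifiability of the reconstructed connectomes).

scenario_names <- function() c("NP_of_reconstructed_FC", "reconstructed_NP_of_FC")

new_scenario_result <- function(scenario, condition, property, profile,
                                optimal_fm, raw_fm = NULL) {
  structure(
    list(scenario = scenario, condition = condition, property = property,
         profile = profile, optimal_fm = optimal_fm, raw_fm = raw_fm),
    class = "scenario_result"
  )
}

#' @export
print.scenario_result <- function(x, ...) {
  opt <- profile_optimum(x$profile)
  cat(sprintf("<scenario_result> %s | condition '%s' | property '%s': m* = %d, I_diff* = %.2f\n",
              x$scenario, x$condition, x$property, opt$m_star, opt$I_diff_star))
  invisible(x)
}

# reconstructed FC columns -> valid connectomes: symmetric by construction of
# the vectorization, diagonal restored to 1, entries clipped back into [-1, 1]
# (reconstruction can overshoot the correlation bounds; clamping of
# non-positive entries to eps happens inside network_properties)
reconstructed_fcs <- function(rec_fm) {
  mats <- devectorize(rec_fm, diag_value = 1)
  lapply(mats, function(m) {
    m[m > 1] <- 1
    m[m < -1] <- -1
    m
  })
}

#' Scenario: network properties of reconstructed connectomes
#'
#' Sweeps the reconstruction level of the connectome feature matrix; at each
#' `m` the reconstructed connectomes are devectorized, their diagonal reset to
#' 1, entries clipped to \[-1, 1\] and non-positive weights clamped, and the
#' requested network properties are computed per run and scored with
#' [identifiability_matrix()].  The identifiability profile of the
#' reconstructed connectomes themselves (the FC baseline) is always produced
#' as well.
#'
#' @param cohort An `fc_cohort` complete for `condition`.
#' @param condition Condition label.
#' @param properties Property names ([network_property_names()]); the special
#'   name `"fc"` is the identity property (the reconstructed connectome
#'   vectors themselves) and reproduces the baseline exactly.
#' @param m_range Component grid, default `1:(2S)`.
#' @param eps_clamp Clamping constant for non-positive weights.
#' @return List with `fc_baseline` (an `idiff_profile`) and `results` (one
#'   `scenario_result` per property).  Each property's cached `optimal_fm`
#'   holds its values at the FC baseline optimum `m*`, the reconstruction
#'   level used for task-sensitivity scoring.
#' @export
scenario_fc_first <- function(cohort, condition,
                              properties = network_property_names("pairwise"),
                              m_range = NULL, eps_clamp = eps_clamp_default()) {
  check_property_names(properties, allow_fc = TRUE)
  fm_fc <- build_feature_matrix(cohort, condition)
  pca <- fit_pca(fm_fc)
  max_m <- ncol(fm_fc$values)
  m_range <- sort(unique(as.integer(m_range %||% seq_len(max_m))))
  if (!length(m_range) || any(m_range < 1) || any(m_range > max_m)) {
    abort(sprintf("`m_range` must be a non-empty subset of [1, %d].", max_m))
  }
  subjects <- fm_fc$subjects
  real_props <- setdiff(properties, "fc")
  base_rows <- vector("list", length(m_range))
  prop_rows <- setNames(rep(list(base_rows), length(properties)), properties)
  for (k in seq_along(m_range)) {
    m <- m_range[k]
    rec <- reconstruct(pca, m)
    r2 <- attr(rec, "r2")
    base_idiff <- identifiability_matrix(rec)$I_diff
    base_rows[[k]] <- tibble(m = m, I_diff = base_idiff, R2 = r2)
    if (length(real_props)) {
      mats <- reconstructed_fcs(rec)
      arrays <- property_arrays_for_runs(mats, real_props, eps_clamp)
    }
    for (p in properties) {
      idiff <- if (p == "fc") {
        base_idiff
      } else {
        fmp <- feature_matrix_from_arrays(arrays[[p]], subjects, condition, p,
                                          vec_kind_for(property_kinds()[[p]]),
                                          fm_fc$n_nodes)
        identifiability_matrix(fmp)$I_diff
      }
      prop_rows[[p]][[k]] <- tibble(m = m, I_diff = idiff, R2 = r2)
    }
  }
  full_idiff <- identifiability_matrix(fm_fc)$I_diff
  fc_baseline <- new_idiff_profile(dplyr::bind_rows(base_rows), full_idiff,
                                   condition, "fc", "FC_baseline")
  # cache each property at the FC optimum: that is the reconstruction level
  # the task-sensitivity assessment uses for this scenario
  m_star_fc <- attr(fc_baseline, "m_star")
  rec_star <- reconstruct(pca, m_star_fc)
  mats_star <- reconstructed_fcs(rec_star)
  arrays_star <- if (length(real_props)) {
    property_arrays_for_runs(mats_star, real_props, eps_clamp)
  } else NULL
  results <- lapply(properties, function(p) {
    full <- if (p == "fc") full_idiff else {
      identifiability_matrix(build_feature_matrix(cohort, condition,
                                                  property = p,
                                                  eps_clamp = eps_clamp))$I_diff
    }
    profile <- new_idiff_profile(dplyr::bind_rows(prop_rows[[p]]), full,
                                 condition, p, "NP_of_reconstructed_FC")
    optimal_fm <- if (p == "fc") rec_star else {
      feature_matrix_from_arrays(arrays_star[[p]], subjects, condition, p,
                                 vec_kind_for(property_kinds()[[p]]),
                                 fm_fc$n_nodes)
    }
    new_scenario_result("NP_of_reconstructed_FC", condition, p, profile, optimal_fm)
  })
  names(results) <- properties
  list(fc_baseline = fc_baseline, results = results)
}

# compute the given properties for every run matrix in a named list
property_arrays_for_runs <- function(mats, properties, eps_clamp) {
  out <- setNames(rep(list(list()), length(properties)), properties)
  for (key in names(mats)) {
    props <- network_properties(mats[[key]], properties, eps_clamp)
    for (p in properties) out[[p]][[key]] <- props[[p]]
  }
  out
}

#' Scenario: reconstructed network properties of original connectomes
#'
#' Computes the property once per run on the original (clamped) connectomes,
#' builds the property feature matrix, and sweeps its own PCA reconstruction.
#'
#' @inheritParams scenario_fc_first
#' @param property A single property name.
#' @return A `scenario_result`; `optimal_fm` is the property feature matrix
#'   reconstructed at its own `m*`, `raw_fm` the unreconstructed one.
#' @export
scenario_np_first <- function(cohort, condition, property,
                              m_range = NULL, eps_clamp = eps_clamp_default()) {
  check_property_names(property)
  stopifnot(length(property) == 1)
  fm <- build_feature_matrix(cohort, condition, property = property,
                             eps_clamp = eps_clamp)
  pca <- fit_pca(fm)
  profile <- sweep_components(fm, m_range, pca = pca)
  attr(profile, "scenario") <- "reconstructed_NP_of_FC"
  optimal <- reconstruct(pca, attr(profile, "m_star"))
  new_scenario_result("reconstructed_NP_of_FC", condition, property, profile,
                      optimal, raw_fm = fm)
}

profile_row <- function(profile, condition, scenario, property) {
  tibble(condition = condition, scenario = scenario, property = property,
         m = profile$m, I_diff = profile$I_diff, R2 = profile$R2)
}

summary_row <- function(profile, condition, scenario, property) {
  opt <- profile_optimum(profile)
  tibble(condition = condition, scenario = scenario, property = property,
         m_star = opt$m_star, I_diff_star = opt$I_diff_star,
         R2_star = opt$R2_star, I_diff_full = opt$I_diff_full)
}

#' Run the full differential-identifiability study
#'
#' For every requested condition: profiles the FC baseline and, per property,
#' the two scenario orders on a common component grid; collects all profiles
#' in one tidy tibble, a Fig-3-style optimum summary, and the reconstructions
#' each variant needs for the task-sensitivity assessment.
#'
#' @param cohort An `fc_cohort`.
#' @param conditions Conditions to analyse; default all in the cohort.
#' @param properties Properties to analyse; default the five pairwise ones.
#' @param scenarios Subset of
#'   `c("NP_of_reconstructed_FC", "reconstructed_NP_of_FC")` (default both).
#' @param m_range Component grid shared by all sweeps; default `1:(2S)`.
#' @param eps_clamp Clamping constant.
#' @return An `idiff_study` with elements `profiles` (tibble
#'   `condition, scenario, property, m, I_diff, R2`), `summary` (tibble
#'   `condition, scenario, property, m_star, I_diff_star, R2_star,
#'   I_diff_full`), and the per-condition cache used by [task_sensitivity()].
#' @examples
#' co <- generate_cohort(cohort_design(
#'   n_subjects = 6, cortical_nodes = 12, subcortical_nodes = 0,
#'   conditions = c("rest1", "motor"), timeseries_length = 80, seed = 3
#' ))
#' st <- run_study(co, properties = "spl", m_range = seq(2, 12, by = 2))
#' st$summary
#' @export
run_study <- function(cohort, conditions = NULL,
                      properties = network_property_names("pairwise"),
                      scenarios = scenario_names(),
                      m_range = NULL, eps_clamp = eps_clamp_default()) {
  stopifnot(inherits(cohort, "fc_cohort"))
  conditions <- conditions %||% cohort_conditions(cohort)
  scenarios <- match.arg(scenarios, scenario_names(), several.ok = TRUE)
  check_property_names(properties)
  profiles <- list()
  summaries <- list()
  cache <- list()
  for (cond in conditions) {
    cond_cache <- list(fc_first = list(), np_first = list(), np_raw = list())
    if ("NP_of_reconstructed_FC" %in% scenarios) {
      ff <- scenario_fc_first(cohort, cond, properties, m_range, eps_clamp)
      profiles <- c(profiles, list(profile_row(ff$fc_baseline, cond, "FC_baseline", "fc")))
      summaries <- c(summaries, list(summary_row(ff$fc_baseline, cond, "FC_baseline", "fc")))
      for (p in properties) {
        res <- ff$results[[p]]
        profiles <- c(profiles, list(profile_row(res$profile, cond, res$scenario, p)))
        summaries <- c(summaries, list(summary_row(res$profile, cond, res$scenario, p)))
        cond_cache$fc_first[[p]] <- res$optimal_fm
      }
    } else {
      # the baseline profile exists for every condition regardless of scenario
      fm_fc <- build_feature_matrix(cohort, cond)
      base <- sweep_components(fm_fc, m_range)
      attr(base, "scenario") <- "FC_baseline"
      profiles <- c(profiles, list(profile_row(base, cond, "FC_baseline", "fc")))
      summaries <- c(summaries, list(summary_row(base, cond, "FC_baseline", "fc")))
    }
    if ("reconstructed_NP_of_FC" %in% scenarios) {
      for (p in properties) {
        res <- scenario_np_first(cohort, cond, p, m_range, eps_clamp)
        profiles <- c(profiles, list(profile_row(res$profile, cond, res$scenario, p)))
        summaries <- c(summaries, list(summary_row(res$profile, cond, res$scenario, p)))
        cond_cache$np_first[[p]] <- res$optimal_fm
        cond_cache$np_raw[[p]] <- res$raw_fm
      }
    } else {
      for (p in properties) {
        cond_cache$np_raw[[p]] <- build_feature_matrix(cohort, cond, property = p,
                                                       eps_clamp = eps_clamp)
      }
    }
    cache[[cond]] <- cond_cache
  }
  structure(
    list(profiles = dplyr::bind_rows(profiles),
         summary = dplyr::bind_rows(summaries),
         cache = cache,
         conditions = conditions, properties = properties,
         scenarios = scenarios, eps_clamp = eps_clamp,
         n_subjects = length(cohort_subjects(cohort)),
         n_nodes = cohort$n_nodes),
    class = "idiff_study"
  )
}

#' @export
print.idiff_study <- function(x, ...) {
  cat(sprintf(
    "<idiff_study> %d conditions x %d properties (%s); S = %d, %d nodes\n",
    length(x$conditions), length(x$properties),
    paste(x$scenarios, collapse = " + "), x$n_subjects, x$n_nodes
  ))
  print(x$summary)
  invisible(x)
}

#' Write study outputs and a provenance record
#'
#' Writes `profiles.csv`, `summary.csv` and a `provenance.json` echoing the
#' study parameters and package version, so a run can be reproduced from its
#' output directory alone.
#'
#' @param study An `idiff_study`.
#' @param dir Output directory (created if needed).
#' @param seed Seed to record in the provenance file, if any randomness was
#'   used upstream (e.g. the cohort design seed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir, seed = NULL) {
  stopifnot(inherits(study, "idiff_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(study$profiles, file.path(dir, "profiles.csv"))
  readr::write_csv(study$summary, file.path(dir, "summary.csv"))
  prov <- list(
    package = "idiffr",
    version = as.character(utils::packageVersion("idiffr")),
    conditions = study$conditions,
    properties = study$properties,
    scenarios = study$scenarios,
    eps_clamp = study$eps_clamp,
    n_subjects = study$n_subjects,
    n_nodes = study$n_nodes,
    seed = seed
  )
  jsonlite::write_json(prov, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}
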