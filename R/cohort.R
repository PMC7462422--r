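#' Default condition labels of a full test-retest design
#'
#' Two resting-state sessions plus seven task conditions; with test and retest
#' runs this yields 18 connectomes per subject.
#'
#' @return Character vector of nine condition labels.
#' @export
default_conditions <- function() {
  c("rest1", "rest2",
    "gambling", "relational", "social", "wm", "motor", "language", "emotion")
}

#' Describe a synthetic test-retest cohort
#'
#' A cohort design fixes everything the generator needs: cohort size,
#' parcellation size, condition labels, time-series length, the three variance
#' weights of the generative mixture, and the seed.  Each run's nodal time
#' series is built as
#' `subject_signal * subject_factor + condition_signal * condition_factor +
#'  noise_signal * run_noise`,
#' where the factors are standard-normal latent series (the subject factor is
#' shared by all of a subject's runs, the condition factor by all runs of a
#' condition, and the noise term is drawn fresh per run); the connectome is
#' the Pearson correlation matrix of those series, hence always symmetric with
#' unit diagonal and entries in \[-1, 1\].
#'
#' @param n_subjects Number of subjects (>= 2).
#' @param cortical_nodes,subcortical_nodes Parcellation sizes; the connectome
#'   has `cortical_nodes + subcortical_nodes` nodes (>= 3 in total).
#' @param conditions Character vector of condition labels (rest sessions count
#'   as conditions).
#' @param timeseries_length Number of synthetic time points per run (>= 2).
#'   Values `<= n_nodes` are accepted with a warning (rank-deficient
#'   connectomes).
#' @param subject_signal,condition_signal,noise_signal Mixture weights in
#'   \[0, 1\]; at least one must be positive.
#' @param seed Integer seed making [generate_cohort()] reproducible.
#' @return A `cohort_design` list.
#' @seealso [generate_cohort()]
#' @export
cohort_design <- function(n_subjects = 100,
                          cortical_nodes = 360,
                          subcortical_nodes = 14,
                          conditions = default_conditions(),
                          timeseries_length = 1200,
                          subject_signal = 0.6,
                          condition_signal = 0.2,
                          noise_signal = 0.4,
                          seed = 1L) {
  n_nodes <- cortical_nodes + subcortical_nodes
  problems <- character()
  if (!is.numeric(n_subjects) || n_subjects < 2) {
    problems <- c(problems, "`n_subjects` must be at least 2.")
  }
  if (cortical_nodes < 0 || subcortical_nodes < 0 || n_nodes < 3) {
    problems <- c(problems, "`n_nodes` (cortical + subcortical) must be at least 3.")
  }
  if (length(conditions) < 1 || anyDuplicated(conditions)) {
    problems <- c(problems, "`conditions` must be a non-empty set of unique labels.")
  }
  if (!is.numeric(timeseries_length) || timeseries_length < 2) {
    problems <- c(problems, "`timeseries_length` must be at least 2.")
  }
  w <- c(subject_signal, condition_signal, noise_signal)
  if (any(w < 0) || any(w > 1)) {
    problems <- c(problems, "signal weights must lie in [0, 1].")
  }
  if (sum(w) <= 0) {
    problems <- c(problems, "at least one signal weight must be positive.")
  }
  if (length(problems)) {
    abort(c("Invalid cohort design:", problems))
  }
  rank_deficient <- timeseries_length <= n_nodes
  if (rank_deficient) {
    warn(sprintf(
      "timeseries_length (%d) <= n_nodes (%d): connectomes will be rank-deficient.",
      as.integer(timeseries_length), as.integer(n_nodes)
    ))
  }
  structure(
    list(
      n_subjects = as.integer(n_subjects),
      cortical_nodes = as.integer(cortical_nodes),
      subcortical_nodes = as.integer(subcortical_nodes),
      n_nodes = as.integer(n_nodes),
      conditions = as.character(conditions),
      runs_per_condition = 2L,
      runs = c("test", "retest"),
      timeseries_length = as.integer(timeseries_length),
      subject_signal = subject_signal,
      condition_signal = condition_signal,
      noise_signal = noise_signal,
      rank_deficient = rank_deficient,
      seed = as.integer(seed)
    ),
    class = "cohort_design"
  )
}

#' @export
print.cohort_design <- function(x, ...) {
  cat(sprintf(
    "<cohort_design> %d subjects x %d conditions x 2 runs, %d nodes, T = %d\n",
    x$n_subjects, length(x$conditions), x$n_nodes, x$timeseries_length
  ))
  cat(sprintf(
    "  weights: subject %.2f, condition %.2f, noise %.2f; seed %d\n",
    x$subject_signal, x$condition_signal, x$noise_signal, x$seed
  ))
  invisible(x)
}

cohort_key <- function(subject_id, condition, run) {
  paste(subject_id, condition, run, sep = "|")
}

new_cohort <- function(matrices, index, n_nodes, design = NULL) {
  structure(
    list(matrices = matrices, index = index, n_nodes = n_nodes, design = design),
    class = "fc_cohort"
  )
}

#' Generate a synthetic test-retest cohort of functional connectomes
#'
#' Draws the latent factors described in [cohort_design()] and returns one
#' Pearson-correlation connectome per (subject, condition, run).  The output
#' is bit-reproducible for a fixed design (including its seed).
#'
#' @param design A [cohort_design()].
#' @return An `fc_cohort`: a keyed list of symmetric correlation matrices plus
#'   an index tibble with columns `subject_id`, `condition`, `run`.
#' @examples
#' co <- generate_cohort(cohort_design(
#'   n_subjects = 4, cortical_nodes = 10, subcortical_nodes = 2,
#'   conditions = c("rest1", "motor"), timeseries_length = 150, seed = 7
#' ))
#' co
#' @export
generate_cohort <- function(design) {
  stopifnot(inherits(design, "cohort_design"))
  n <- design$n_nodes
  tt <- design$timeseries_length
  subjects <- sprintf("sub%03d", seq_len(design$n_subjects))

  set.seed(design$seed)
  # draw order is fixed (subject factors, condition factors, then run noise in
  # nested loop order) so that the same seed always yields the same cohort and
  # changing only the mixture weights reuses identical latent draws
  subj_factors <- lapply(subjects, function(s) matrix(stats::rnorm(n * tt), n, tt))
  names(subj_factors) <- subjects
  cond_factors <- lapply(design$conditions, function(cc) matrix(stats::rnorm(n * tt), n, tt))
  names(cond_factors) <- design$conditions

  a <- design$subject_signal
  b <- design$condition_signal
  cc <- design$noise_signal

  matrices <- list()
  rows <- list()
  for (s in subjects) {
    for (cond in design$conditions) {
      for (run in design$runs) {
        noise <- matrix(stats::rnorm(n * tt), n, tt)
        x <- a * subj_factors[[s]] + b * cond_factors[[cond]] + cc * noise
        v <- stats::cor(t(x))
        v <- (v + t(v)) / 2
        v[v > 1] <- 1
        v[v < -1] <- -1
        diag(v) <- 1
        key <- cohort_key(s, cond, run)
        matrices[[key]] <- v
        rows[[key]] <- tibble(subject_id = s, condition = cond, run = run)
      }
    }
  }
  new_cohort(matrices, dplyr::bind_rows(rows), n, design)
}

#' @export
print.fc_cohort <- function(x, ...) {
  cat(sprintf(
    "<fc_cohort> %d matrices (%d x %d): %d subjects, %d conditions, runs test/retest\n",
    nrow(x$index), x$n_nodes, x$n_nodes,
    dplyr::n_distinct(x$index$subject_id), dplyr::n_distinct(x$index$condition)
  ))
  invisible(x)
}

#' Extract one connectome from a cohort
#'
#' @param cohort An `fc_cohort`.
#' @param subject_id,condition,run Identifiers of the requested matrix.
#' @return A symmetric correlation matrix.
#' @export
cohort_matrix <- function(cohort, subject_id, condition, run) {
  key <- cohort_key(subject_id, condition, run)
  m <- cohort$matrices[[key]]
  if (is.null(m)) {
    abort(sprintf("No connectome stored for subject '%s', condition '%s', run '%s'.",
                  subject_id, condition, run))
  }
  m
}

#' Subjects and conditions present in a cohort
#' @param cohort An `fc_cohort`.
#' @return Sorted character vector.
#' @export
cohort_subjects <- function(cohort) sort(unique(cohort$index$subject_id))

#' @rdname cohort_subjects
#' @export
cohort_conditions <- function(cohort) unique(cohort$index$condition)

#' Write a cohort to delimited matrix files plus a manifest
#'
#' One plain comma-separated full square matrix per (subject, condition, run),
#' no header, and a `manifest.csv` with columns
#' `subject_id,condition,run,path` (paths relative to the manifest).
#'
#' @param cohort An `fc_cohort`.
#' @param dir Output directory (created if needed).
#' @return The manifest tibble, invisibly; the manifest file is
#'   `file.path(dir, "manifest.csv")`.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "fc_cohort"))
  if (nrow(cohort$index) == 0) abort("Cannot write an empty cohort.")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) abort(sprintf("Cannot create output directory '%s'.", dir))
  manifest <- cohort$index |>
    dplyr::mutate(path = sprintf("%s_%s_%s.csv", .data$subject_id, .data$condition, .data$run))
  for (i in seq_len(nrow(manifest))) {
    key <- cohort_key(manifest$subject_id[i], manifest$condition[i], manifest$run[i])
    write_fc_file(cohort$matrices[[key]], file.path(dir, manifest$path[i]))
  }
  readr::write_csv(manifest, file.path(dir, "manifest.csv"))
  invisible(manifest)
}

# 17 significant digits round-trip IEEE doubles exactly
write_fc_file <- function(m, path) {
  writeLines(apply(m, 1, function(r) paste(sprintf("%.17g", r), collapse = ",")),
             path)
}

read_fc_file <- function(path) {
  # base scan(): correctly rounded strtod parsing, exact round-trip with %.17g
  vals <- scan(path, what = numeric(), sep = ",", quiet = TRUE)
  n <- as.integer(sqrt(length(vals)))
  if (n * n != length(vals)) {
    abort(sprintf("Matrix file '%s' is not square (%d values).", path, length(vals)))
  }
  matrix(vals, n, n, byrow = TRUE)
}

#' Read a cohort from a manifest of delimited matrix files
#'
#' Validates the store on the way in: the manifest must pair a test and a
#' retest run for every (subject, condition); each matrix must be square,
#' symmetric within `tol`, with off-diagonal entries in \[-1, 1\]; all
#' matrices must share one dimension.
#'
#' @param manifest Path to a manifest CSV with header
#'   `subject_id,condition,run,path` (paths resolved relative to the
#'   manifest), or a data frame of the same shape with absolute paths.
#' @param tol Symmetry tolerance.
#' @return An `fc_cohort`.
#' @export
read_cohort <- function(manifest, tol = 1e-8) {
  if (is.character(manifest)) {
    base <- dirname(manifest)
    man <- readr::read_csv(manifest, col_types = readr::cols(.default = readr::col_character()),
                           progress = FALSE)
    man$path <- file.path(base, man$path)
  } else {
    man <- as_tibble(manifest)
  }
  need <- c("subject_id", "condition", "run", "path")
  if (!all(need %in% names(man))) {
    abort(sprintf("Manifest must have columns %s.", paste(need, collapse = ", ")))
  }
  if (!all(man$run %in% c("test", "retest"))) {
    abort("Manifest column `run` may only contain 'test' and 'retest'.")
  }
  pairing <- man |>
    dplyr::count(.data$subject_id, .data$condition) |>
    dplyr::filter(.data$n != 2)
  runs_ok <- man |>
    dplyr::distinct(.data$subject_id, .data$condition, .data$run) |>
    dplyr::count(.data$subject_id, .data$condition) |>
    dplyr::filter(.data$n != 2)
  if (nrow(pairing) || nrow(runs_ok)) {
    bad <- dplyr::bind_rows(pairing, runs_ok) |> dplyr::distinct(.data$subject_id, .data$condition)
    abort(c(
      "Every (subject, condition) needs exactly one test and one retest run; incomplete pairs:",
      sprintf("subject '%s', condition '%s'", bad$subject_id, bad$condition)
    ))
  }
  matrices <- list()
  n_nodes <- NULL
  for (i in seq_len(nrow(man))) {
    p <- man$path[i]
    if (!file.exists(p)) abort(sprintf("Matrix file '%s' does not exist.", p))
    m <- read_fc_file(p)
    if (nrow(m) != ncol(m)) abort(sprintf("Matrix in '%s' is not square.", p))
    if (max(abs(m - t(m))) > tol) {
      abort(sprintf("Matrix in '%s' is not symmetric within %g.", p, tol))
    }
    off <- m[row(m) != col(m)]
    if (any(off < -1 - tol) || any(off > 1 + tol)) {
      abort(sprintf("Matrix in '%s' has off-diagonal entries outside [-1, 1].", p))
    }
    if (is.null(n_nodes)) {
      n_nodes <- nrow(m)
    } else if (nrow(m) != n_nodes) {
      abort(sprintf("Matrix in '%s' is %d x %d but the cohort dimension is %d.",
                    p, nrow(m), ncol(m), n_nodes))
    }
    matrices[[cohort_key(man$subject_id[i], man$condition[i], man$run[i])]] <- m
  }
  new_cohort(matrices,
             dplyr::select(man, "subject_id", "condition", "run"),
             n_nodes)
}
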