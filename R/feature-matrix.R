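## Vectorization of connectomes / property arrays into feature columns.
## Kinds:
##   fc_upper_triangle         - symmetric matrix, unit diagonal implied
##   pairwise_symmetric_upper  - symmetric property, zero diagonal implied
##   pairwise_asymmetric_offdiag - all n(n-1) ordered pairs, column-major
##   node_vector               - length-n vector

vec_kind_for <- function(property_kind) {
  switch(property_kind,
    node                = "node_vector",
    pairwise_symmetric  = "pairwise_symmetric_upper",
    pairwise_asymmetric = "pairwise_asymmetric_offdiag",
    abort(sprintf("Unknown property kind '%s'.", property_kind))
  )
}

feature_labels <- function(kind, n) {
  idx <- switch(kind,
    node_vector = return(sprintf("(%d)", seq_len(n))),
    fc_upper_triangle = ,
    pairwise_symmetric_upper = which(upper.tri(matrix(0, n, n))),
    pairwise_asymmetric_offdiag = which(row(matrix(0, n, n)) != col(matrix(0, n, n)))
  )
  i <- ((idx - 1) %% n) + 1
  j <- ((idx - 1) %/% n) + 1
  sprintf("(%d,%d)", i, j)
}

vectorize_array <- function(x, kind) {
  switch(kind,
    node_vector = as.numeric(x),
    fc_upper_triangle = ,
    pairwise_symmetric_upper = x[upper.tri(x)],
    pairwise_asymmetric_offdiag = x[row(x) != col(x)]
  )
}

devectorize_array <- function(v, kind, n, diag_value = NULL) {
  switch(kind,
    node_vector = as.numeric(v),
    fc_upper_triangle = {
      m <- matrix(0, n, n)
      m[upper.tri(m)] <- v
      m <- m + t(m)
      diag(m) <- diag_value %||% 1
      m
    },
    pairwise_symmetric_upper = {
      m <- matrix(0, n, n)
      m[upper.tri(m)] <- v
      m <- m + t(m)
      diag(m) <- diag_value %||% 0
      m
    },
    pairwise_asymmetric_offdiag = {
      m <- matrix(0, n, n)
      m[row(m) != col(m)] <- v
      diag(m) <- diag_value %||% 0
      m
    }
  )
}

features_per_kind <- function(kind, n) {
  switch(kind,
    node_vector = n,
    fc_upper_triangle = ,
    pairwise_symmetric_upper = n * (n - 1) / 2,
    pairwise_asymmetric_offdiag = n * (n - 1)
  )
}

new_feature_matrix <- function(values, subjects, kind, n_nodes, condition, property) {
  s <- length(subjects)
  column_meta <- tibble(
    subject_id = rep(subjects, times = 2),
    run = rep(c("test", "retest"), each = s),
    column = seq_len(2 * s)
  )
  colnames(values) <- paste(column_meta$subject_id, column_meta$run, sep = "|")
  structure(
    list(values = values, subjects = subjects, column_meta = column_meta,
         kind = kind, n_nodes = n_nodes, condition = condition, property = property),
    class = "feature_matrix"
  )
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf(
    "<feature_matrix> %d features x %d runs (%d subjects), kind '%s', condition '%s', property '%s'\n",
    nrow(x$values), ncol(x$values), length(x$subjects), x$kind,
    x$condition %||% "?", x$property %||% "fc"
  ))
  invisible(x)
}

run_key <- function(subject_id, run) paste(subject_id, run, sep = "|")

# compute the requested properties for every run of one condition, sharing the
# per-graph preparation across properties
cohort_condition_properties <- function(cohort, condition, properties, eps_clamp) {
  subjects <- cohort_subjects(cohort)
  out <- lapply(properties, function(p) list())
  names(out) <- properties
  for (s in subjects) {
    for (run in c("test", "retest")) {
      fc <- cohort_matrix(cohort, s, condition, run)
      props <- network_properties(fc, properties, eps_clamp)
      for (p in properties) out[[p]][[run_key(s, run)]] <- props[[p]]
    }
  }
  out
}

#' Assemble the features x runs matrix of one condition
#'
#' Vectorizes either the connectomes themselves (`property = NULL`: upper
#' triangle, diagonal excluded) or a network property computed on each clamped
#' connectome (symmetric pairwise: upper triangle; asymmetric pairwise: all
#' `n(n-1)` ordered pairs; node: the vector itself).  Columns are the 2S runs
#' of the condition: the test block then the retest block, subjects sorted, so
#' test/retest pairing is always recoverable from `column_meta`.
#'
#' @param cohort An `fc_cohort` in which every subject has both runs of
#'   `condition`.
#' @param condition Condition label present in the cohort.
#' @param property `NULL` for the connectome itself, or one property name from
#'   [network_property_names()].
#' @param eps_clamp Clamping constant applied before property computation
#'   (never applied to the raw connectome features).
#' @return A `feature_matrix` with fields `values` (F x 2S), `column_meta`,
#'   `kind`, `n_nodes`.
#' @export
build_feature_matrix <- function(cohort, condition, property = NULL,
                                 eps_clamp = eps_clamp_default()) {
  stopifnot(inherits(cohort, "fc_cohort"))
  if (!condition %in% cohort$index$condition) {
    abort(sprintf("Condition '%s' is not present in the cohort.", condition))
  }
  subjects <- cohort_subjects(cohort)
  idx <- cohort$index[cohort$index$condition == condition, ]
  for (s in subjects) {
    runs <- idx$run[idx$subject_id == s]
    if (!all(c("test", "retest") %in% runs)) {
      abort(sprintf("Subject '%s' is missing a run for condition '%s'.", s, condition))
    }
  }
  n <- cohort$n_nodes
  if (is.null(property)) {
    kind <- "fc_upper_triangle"
    cols <- lapply(c("test", "retest"), function(run) {
      vapply(subjects,
             function(s) vectorize_array(cohort_matrix(cohort, s, condition, run), kind),
             numeric(features_per_kind(kind, n)))
    })
    values <- do.call(cbind, cols)
    return(new_feature_matrix(values, subjects, kind, n, condition, NULL))
  }
  check_property_names(property)
  stopifnot(length(property) == 1)
  kind <- vec_kind_for(property_kinds()[[property]])
  arrays <- cohort_condition_properties(cohort, condition, property, eps_clamp)[[property]]
  cols <- lapply(c("test", "retest"), function(run) {
    vapply(subjects,
           function(s) vectorize_array(arrays[[run_key(s, run)]], kind),
           numeric(features_per_kind(kind, n)))
  })
  new_feature_matrix(do.call(cbind, cols), subjects, kind, n, condition, property)
}

# build a feature matrix directly from per-run arrays (used by the pipeline
# after computing properties on reconstructed connectomes)
feature_matrix_from_arrays <- function(arrays, subjects, condition, property, kind, n) {
  cols <- lapply(c("test", "retest"), function(run) {
    vapply(subjects,
           function(s) vectorize_array(arrays[[run_key(s, run)]], kind),
           numeric(features_per_kind(kind, n)))
  })
  new_feature_matrix(do.call(cbind, cols), subjects, kind, n, condition, property)
}

#' Invert the vectorization of a feature matrix
#'
#' @param fm A `feature_matrix`.
#' @param diag_value Diagonal restored on devectorized matrices (1 for
#'   connectomes, 0 for pairwise properties).
#' @return Named list (one element per run column, `subject|run`) of matrices
#'   or node vectors.
#' @export
devectorize <- function(fm, diag_value = NULL) {
  stopifnot(inherits(fm, "feature_matrix"))
  out <- lapply(seq_len(ncol(fm$values)), function(j) {
    devectorize_array(fm$values[, j], fm$kind, fm$n_nodes, diag_value)
  })
  names(out) <- colnames(fm$values)
  out
}
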