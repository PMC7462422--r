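#' Tidy an identifiability profile
#'
#' @param x An `idiff_profile`.
#' @param ... Unused.
#' @return A plain tibble with columns `m`, `I_diff`, `R2`.
#' @method tidy idiff_profile
#' @export
tidy.idiff_profile <- function(x, ...) {
  as_tibble(as.data.frame(x))
}

#' One-row summary of an identifiability profile
#'
#' @inheritParams tidy.idiff_profile
#' @return A tibble with `m_star`, `I_diff_star`, `R2_star`, `I_diff_full`.
#' @method glance idiff_profile
#' @export
glance.idiff_profile <- function(x, ...) {
  opt <- profile_optimum(x)
  tibble(m_star = opt$m_star, I_diff_star = opt$I_diff_star,
         R2_star = opt$R2_star, I_diff_full = opt$I_diff_full)
}

#' Tidy an identifiability matrix into long form
#'
#' @param x An `identifiability_result`.
#' @param ... Unused.
#' @return Tibble with columns `test_subject`, `retest_subject`,
#'   `correlation`, `pair` (`"self"` on the diagonal).
#' @method tidy identifiability_result
#' @export
tidy.identifiability_result <- function(x, ...) {
  im <- x$matrix
  tibble(
    test_subject = rep(rownames(im), times = ncol(im)),
    retest_subject = rep(colnames(im), each = nrow(im)),
    correlation = as.vector(im)
  ) |>
    dplyr::mutate(pair = ifelse(.data$test_subject == .data$retest_subject,
                                "self", "others"))
}

#' One-row summary of an identifiability result
#'
#' @inheritParams tidy.identifiability_result
#' @return Tibble with `I_self`, `I_others`, `I_diff`, `n_subjects`.
#' @method glance identifiability_result
#' @export
glance.identifiability_result <- function(x, ...) {
  tibble(I_self = x$I_self, I_others = x$I_others, I_diff = x$I_diff,
         n_subjects = length(x$subjects))
}

#' Tidy a PCA fit: one row per component
#'
#' @param x An `if_pca`.
#' @param ... Unused.
#' @return Tibble with `component`, `sdev`, `variance_fraction`,
#'   `cumulative_r2`.
#' @method tidy if_pca
#' @export
tidy.if_pca <- function(x, ...) {
  total <- sum(x$d^2)
  tibble(
    component = seq_along(x$d),
    sdev = x$d / sqrt(max(1, x$max_m - 1)),
    variance_fraction = if (total > 0) x$d^2 / total else rep(0, length(x$d)),
    cumulative_r2 = x$r2_cum
  )
}

#' One-row summary of a PCA fit
#'
#' @inheritParams tidy.if_pca
#' @return Tibble with `n_features`, `n_runs`, `n_components`.
#' @method glance if_pca
#' @export
glance.if_pca <- function(x, ...) {
  tibble(n_features = nrow(x$u), n_runs = x$max_m, n_components = x$n_components)
}

#' Tidy a study into its profile table
#'
#' @param x An `idiff_study`.
#' @param ... Unused.
#' @return The tidy profiles tibble
#'   (`condition, scenario, property, m, I_diff, R2`).
#' @method tidy idiff_study
#' @export
tidy.idiff_study <- function(x, ...) x$profiles

#' One-row overview of a study
#'
#' @inheritParams tidy.idiff_study
#' @return Tibble with study dimensions.
#' @method glance idiff_study
#' @export
glance.idiff_study <- function(x, ...) {
  tibble(n_conditions = length(x$conditions),
         n_properties = length(x$properties),
         n_subjects = x$n_subjects,
         n_nodes = x$n_nodes)
}
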