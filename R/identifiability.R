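#' Group-level PCA of a feature matrix
#'
#' Centers each feature on its mean across the 2S run columns (the group
#' average is what all subjects share), then takes the singular value
#' decomposition of the centered matrix.  Components are ordered by explained
#' variance; each component's sign is fixed so that its largest-magnitude
#' coordinate is positive, making the decomposition deterministic.
#'
#' @param fm A `feature_matrix` (F features x 2S runs).
#' @return An `if_pca` object: mean vector, left/right singular vectors,
#'   singular values, cumulative explained-variance fractions, and the source
#'   feature matrix.
#' @export
fit_pca <- function(fm) {
  stopifnot(inherits(fm, "feature_matrix"))
  x <- fm$values
  if (ncol(x) < 2) abort("PCA needs at least two run columns.")
  mu <- rowMeans(x)
  sv <- svd(x - mu)
  for (j in seq_along(sv$d)) {
    i <- which.max(abs(sv$u[, j]))
    if (sv$u[i, j] < 0) {
      sv$u[, j] <- -sv$u[, j]
      sv$v[, j] <- -sv$v[, j]
    }
  }
  total <- sum(sv$d^2)
  r2 <- if (total > 0) cumsum(sv$d^2) / total else rep(1, length(sv$d))
  structure(
    list(mean = mu, u = sv$u, d = sv$d, v = sv$v, r2_cum = r2,
         n_components = length(sv$d), max_m = ncol(x), fm = fm),
    class = "if_pca"
  )
}

#' @export
print.if_pca <- function(x, ...) {
  cat(sprintf("<if_pca> %d features, %d runs, %d components\n",
              nrow(x$u), x$max_m, x$n_components))
  invisible(x)
}

#' Cumulative explained variance at m components
#'
#' @param pca An [fit_pca()] object.
#' @param m Number of retained components (1..2S).
#' @return Fraction of variance retained, in \[0, 1\].
#' @export
explained_variance <- function(pca, m) {
  stopifnot(inherits(pca, "if_pca"))
  m <- check_m(pca, m)
  pca$r2_cum[min(m, pca$n_components)]
}

check_m <- function(pca, m) {
  if (!is.numeric(m) || length(m) != 1 || m != round(m) || m < 1 || m > pca$max_m) {
    abort(sprintf("`m` must be an integer in [1, %d].", pca$max_m))
  }
  as.integer(m)
}

#' Reconstruct the feature matrix from its top-m components
#'
#' Adds the feature mean back after expanding the m highest-variance
#' components; at `m = 2S` the input is recovered (up to numerical error).
#'
#' @inheritParams explained_variance
#' @return A `feature_matrix` with reconstructed values and unchanged
#'   metadata; attribute `m` records the reconstruction level and `r2` the
#'   variance retained.
#' @export
reconstruct <- function(pca, m) {
  stopifnot(inherits(pca, "if_pca"))
  m <- check_m(pca, m)
  mm <- min(m, pca$n_components)
  keep <- seq_len(mm)
  vals <- pca$mean +
    pca$u[, keep, drop = FALSE] %*% (pca$d[keep] * t(pca$v[, keep, drop = FALSE]))
  out <- pca$fm
  out$values <- unname(vals)
  colnames(out$values) <- colnames(pca$fm$values)
  attr(out, "m") <- m
  attr(out, "r2") <- explained_variance(pca, m)
  out
}

#' Identifiability matrix and differential identifiability
#'
#' Entry (i, j) of the S x S identifiability matrix is the Pearson
#' correlation, across features, between subject i's test column and subject
#' j's retest column.  `I_self` is the mean diagonal, `I_others` the mean of
#' the S(S-1) off-diagonal entries, and
#' `I_diff = (I_self - I_others) * 100`.
#'
#' @param fm A `feature_matrix`.
#' @return An `identifiability_result` with the matrix and the three scores.
#' @export
identifiability_matrix <- function(fm) {
  stopifnot(inherits(fm, "feature_matrix"))
  x <- fm$values
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    bad <- colnames(x)[sds == 0]
    abort(c("Pearson correlation undefined for zero-variance run column(s):", bad))
  }
  s <- length(fm$subjects)
  im <- stats::cor(x[, seq_len(s), drop = FALSE], x[, s + seq_len(s), drop = FALSE])
  dimnames(im) <- list(test = fm$subjects, retest = fm$subjects)
  i_self <- mean(diag(im))
  i_others <- (sum(im) - sum(diag(im))) / (s * (s - 1))
  structure(
    list(matrix = im, subjects = fm$subjects,
         I_self = i_self, I_others = i_others,
         I_diff = 100 * (i_self - i_others),
         condition = fm$condition, property = fm$property),
    class = "identifiability_result"
  )
}

#' @export
print.identifiability_result <- function(x, ...) {
  cat(sprintf("<identifiability> S = %d: I_self = %.4f, I_others = %.4f, I_diff = %.2f\n",
              length(x$subjects), x$I_self, x$I_others, x$I_diff))
  invisible(x)
}

#' Permutation null distribution of I_diff
#'
#' Re-pairs test and retest columns by permuting the subject labels of the
#' retest side of an identifiability matrix and recomputes `I_diff` for each
#' permutation.  Under the null of no subject fingerprint the observed
#' `I_diff` is exchangeable with these values.
#'
#' @param ident An [identifiability_matrix()] result.
#' @param n_perm Number of label permutations (>= 100 recommended).
#' @return Numeric vector of permuted `I_diff` values.
#' @export
idiff_permutation_null <- function(ident, n_perm = 200) {
  stopifnot(inherits(ident, "identifiability_result"))
  im <- ident$matrix
  s <- nrow(im)
  total <- sum(im)
  vapply(seq_len(n_perm), function(i) {
    perm <- sample.int(s)
    self <- mean(im[cbind(seq_len(s), perm)])
    others <- (total - s * self) / (s * (s - 1))
    100 * (self - others)
  }, numeric(1))
}

#' Sweep the number of retained components and profile I_diff
#'
#' Reconstructs the feature matrix at each `m` in the grid and records
#' `I_diff` and the retained variance; the optimum `m*` is the smallest
#' argmax of `I_diff`.  `I_diff` of the unreconstructed data (equivalently,
#' full reconstruction at `m = 2S`) is kept alongside.
#'
#' @param fm A `feature_matrix`.
#' @param m_range Integer vector of component counts in `[1, 2S]`; default the
#'   full grid `1:2S`.  A stride (e.g. `seq(2, 2*S, by = 2)`) trades grid
#'   resolution for speed.
#' @param pca Optional precomputed [fit_pca()] fit of `fm`.
#' @return An `idiff_profile`: a tibble with columns `m`, `I_diff`, `R2` and
#'   attributes `m_star`, `I_diff_star`, `R2_star`, `I_diff_full`.
#' @export
sweep_components <- function(fm, m_range = NULL, pca = NULL) {
  stopifnot(inherits(fm, "feature_matrix"))
  max_m <- ncol(fm$values)
  m_range <- m_range %||% seq_len(max_m)
  m_range <- sort(unique(as.integer(m_range)))
  if (length(m_range) == 0) abort("`m_range` is empty.")
  if (any(m_range < 1) || any(m_range > max_m)) {
    abort(sprintf("`m_range` must lie within [1, %d].", max_m))
  }
  if (is.null(pca)) pca <- fit_pca(fm)
  rows <- lapply(m_range, function(m) {
    rec <- reconstruct(pca, m)
    tibble(m = m,
           I_diff = identifiability_matrix(rec)$I_diff,
           R2 = attr(rec, "r2"))
  })
  profile <- dplyr::bind_rows(rows)
  new_idiff_profile(profile,
                    I_diff_full = identifiability_matrix(fm)$I_diff,
                    condition = fm$condition, property = fm$property)
}

new_idiff_profile <- function(profile, I_diff_full, condition = NULL,
                              property = NULL, scenario = NULL) {
  star <- which.max(profile$I_diff) # which.max takes the first (smallest m) on ties
  structure(
    profile,
    class = c("idiff_profile", class(profile)),
    m_star = profile$m[star],
    I_diff_star = profile$I_diff[star],
    R2_star = profile$R2[star],
    I_diff_full = I_diff_full,
    condition = condition, property = property, scenario = scenario
  )
}

#' Optimal reconstruction level of a profile
#'
#' @param profile An `idiff_profile`.
#' @return Named list with `m_star`, `I_diff_star`, `R2_star`, `I_diff_full`.
#' @export
profile_optimum <- function(profile) {
  stopifnot(inherits(profile, "idiff_profile"))
  list(m_star = attr(profile, "m_star"),
       I_diff_star = attr(profile, "I_diff_star"),
       R2_star = attr(profile, "R2_star"),
       I_diff_full = attr(profile, "I_diff_full"))
}

#' @export
print.idiff_profile <- function(x, ...) {
  opt <- profile_optimum(x)
  cat(sprintf(
    "<idiff_profile> %d reconstruction levels; m* = %d, I_diff* = %.2f (R2 = %.3f), I_diff(full) = %.2f\n",
    nrow(x), opt$m_star, opt$I_diff_star, opt$R2_star, opt$I_diff_full
  ))
  NextMethod()
}
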