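#' One-way random-effects intraclass correlation, ICC(1,1)
#'
#' `ICC = (MSB - MSW) / (MSB + (k - 1) MSW)` from the one-way ANOVA
#' decomposition, where groups are rated by k unordered replicates each.
#' Negative values are retained (the one-way lower bound is `-1/(k-1)`); a
#' group set with zero total variance has no defined ICC and yields `NA`.
#'
#' @param groups A list of equal-length numeric vectors (one per group), or a
#'   matrix with one row per group.
#' @return A single ICC value in \[-1, 1\], or `NA_real_` when undefined.
#' @examples
#' icc_oneway(list(c(1, 1), c(2, 2), c(3, 3)))   # perfect agreement: 1
#' icc_oneway(list(c(0, 1), c(1, 0)))            # equal group means: -1
#' @export
icc_oneway <- function(groups) {
  if (is.list(groups)) {
    k <- unique(lengths(groups))
    if (length(k) != 1) abort("All groups must have the same number of members.")
    x <- do.call(rbind, groups)
  } else if (is.matrix(groups)) {
    x <- groups
    k <- ncol(x)
  } else {
    abort("`groups` must be a list of numeric vectors or a matrix.")
  }
  if (nrow(x) < 2) abort("ICC needs at least two groups.")
  if (k < 2) abort("ICC needs at least two members per group.")
  gm <- rowMeans(x)
  grand <- mean(x)
  ssb <- k * sum((gm - grand)^2)
  ssw <- sum((x - gm)^2)
  if (ssb + ssw <= 0) return(NA_real_)
  msb <- ssb / (nrow(x) - 1)
  msw <- ssw / (nrow(x) * (k - 1))
  (msb - msw) / (msb + (k - 1) * msw)
}

variant_names <- function() {
  c("NP_of_reconstructed_FC", "reconstructed_NP_of_FC", "NP_of_original_FC")
}

variant_cache_slot <- function(variant) {
  switch(variant,
    NP_of_reconstructed_FC = "fc_first",
    reconstructed_NP_of_FC = "np_first",
    NP_of_original_FC = "np_raw"
  )
}

# feature x subject x run x condition array for one (property, variant)
variant_array <- function(study, property, variant) {
  slot <- variant_cache_slot(variant)
  fms <- lapply(study$conditions, function(cond) {
    fm <- study$cache[[cond]][[slot]][[property]]
    if (is.null(fm)) {
      abort(sprintf(
        "Study cache has no %s reconstruction of property '%s' for condition '%s'; rerun run_study() with the matching scenario.",
        variant, property, cond
      ))
    }
    fm
  })
  s <- length(fms[[1]]$subjects)
  f <- nrow(fms[[1]]$values)
  x <- array(NA_real_, dim = c(f, s, 2, length(fms)))
  for (ci in seq_along(fms)) {
    v <- fms[[ci]]$values
    x[, , 1, ci] <- v[, seq_len(s)]          # test block
    x[, , 2, ci] <- v[, s + seq_len(s)]      # retest block
  }
  list(x = x, labels = feature_labels(fms[[1]]$kind, fms[[1]]$n_nodes))
}

# vectorized one-way ICC over the first two margins of x[f, s, run, cond]:
# groups = conditions, members = the two runs
icc_array <- function(x) {
  f <- dim(x)[1]; s <- dim(x)[2]; nc <- dim(x)[4]
  gm <- (x[, , 1, , drop = FALSE] + x[, , 2, , drop = FALSE]) / 2
  gm <- array(gm, dim = c(f, s, nc))
  grand <- apply(gm, c(1, 2), mean)
  ssb <- 2 * apply((gm - as.vector(grand))^2, c(1, 2), sum)
  dev <- sweep(x, c(1, 2, 4), gm, `-`)
  ssw <- apply(dev^2, c(1, 2), sum)
  msb <- ssb / (nc - 1)
  msw <- ssw / nc                       # df = C * (k - 1) with k = 2
  icc <- (msb - msw) / (msb + msw)
  icc[ssb + ssw <= 0] <- NA_real_
  icc
}

#' Task sensitivity of network properties via ICC
#'
#' For every feature (node pair or node) and subject, the one-way ICC is
#' computed with the study's conditions as groups and the subject's test and
#' retest values as the two members of each group; the mean across subjects
#' is reported per feature.  Each variant scores the values it defines:
#' properties of connectomes reconstructed at the FC-baseline optimum
#' (`NP_of_reconstructed_FC`), properties reconstructed at their own optimum
#' (`reconstructed_NP_of_FC`), or unreconstructed properties of the original
#' connectomes (`NP_of_original_FC`).
#'
#' @param study An [run_study()] result whose scenarios cover the requested
#'   variants and with at least two conditions.
#' @param variants Subset of
#'   `c("NP_of_reconstructed_FC", "reconstructed_NP_of_FC",
#'   "NP_of_original_FC")`; default all three.
#' @param properties Properties to score; default those of the study.
#' @return An `icc_table` tibble with columns `property`, `variant`,
#'   `feature_id`, `mean_icc`.
#' @export
task_sensitivity <- function(study, variants = variant_names(),
                             properties = NULL) {
  stopifnot(inherits(study, "idiff_study"))
  variants <- match.arg(variants, variant_names(), several.ok = TRUE)
  properties <- properties %||% study$properties
  if (length(study$conditions) < 2) {
    abort("Task sensitivity needs at least two conditions as ICC groups.")
  }
  rows <- list()
  for (p in properties) {
    for (v in variants) {
      va <- variant_array(study, p, v)
      icc <- icc_array(va$x)
      rows[[paste(p, v)]] <- tibble(
        property = p, variant = v,
        feature_id = va$labels,
        mean_icc = rowMeans(icc, na.rm = TRUE)
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("icc_table", class(out))
  out
}
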