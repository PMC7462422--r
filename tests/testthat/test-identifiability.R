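test_that("vectorization kinds have the right lengths and invert exactly", {
  n <- 7
  sym <- matrix(stats::rnorm(n * n), n, n); sym <- (sym + t(sym)) / 2; diag(sym) <- 0
  fc <- sym; diag(fc) <- 1
  asym <- matrix(stats::rnorm(n * n), n, n); diag(asym) <- 0
  nodev <- stats::rnorm(n)

  v <- idiffr:::vectorize_array(fc, "fc_upper_triangle")
  expect_length(v, n * (n - 1) / 2)
  expect_identical(idiffr:::devectorize_array(v, "fc_upper_triangle", n), fc)

  v <- idiffr:::vectorize_array(sym, "pairwise_symmetric_upper")
  expect_length(v, n * (n - 1) / 2)
  expect_identical(idiffr:::devectorize_array(v, "pairwise_symmetric_upper", n), sym)

  v <- idiffr:::vectorize_array(asym, "pairwise_asymmetric_offdiag")
  expect_length(v, n * (n - 1))
  expect_identical(idiffr:::devectorize_array(v, "pairwise_asymmetric_offdiag", n), asym)

  v <- idiffr:::vectorize_array(nodev, "node_vector")
  expect_length(v, n)
  expect_identical(idiffr:::devectorize_array(v, "node_vector", n), nodev)

  labs <- idiffr:::feature_labels("pairwise_asymmetric_offdiag", 3)
  expect_length(labs, 6)
  expect_true(all(grepl("^\\(\\d,\\d\\)$", labs)))
})

test_that("feature matrices index columns as test block then retest block", {
  co <- tiny_cohort(n_subjects = 3, n_nodes = 8, conditions = "c1", seed = 6)
  fm <- build_feature_matrix(co, "c1")
  expect_equal(dim(fm$values), c(8 * 7 / 2, 6))
  expect_equal(fm$column_meta$run, rep(c("test", "retest"), each = 3))
  expect_equal(fm$column_meta$subject_id, rep(sprintf("sub%03d", 1:3), 2))
  expect_identical(fm$values[, 1],
                   idiffr:::vectorize_array(cohort_matrix(co, "sub001", "c1", "test"),
                                            "fc_upper_triangle"))
  fm_node <- build_feature_matrix(co, "c1", property = "strength")
  expect_equal(nrow(fm_node$values), 8)
  fm_asym <- build_feature_matrix(co, "c1", property = "mfpt")
  expect_equal(nrow(fm_asym$values), 8 * 7)

  expect_error(build_feature_matrix(co, "nope"), "not present")
  co2 <- co
  drop <- which(co2$index$subject_id == "sub002" & co2$index$run == "retest")
  co2$index <- co2$index[-drop, ]
  expect_error(build_feature_matrix(co2, "c1"), "missing a run")
})

test_that("PCA reconstruction identities hold", {
  set.seed(10)
  co <- tiny_cohort(n_subjects = 4, n_nodes = 10, conditions = "c1", seed = 10)
  fm <- build_feature_matrix(co, "c1")
  pca <- fit_pca(fm)

  expect_equal(sum(tidy(pca)$variance_fraction), 1, tolerance = 1e-12)
  expect_true(all(diff(pca$r2_cum) >= -1e-12))
  expect_equal(explained_variance(pca, ncol(fm$values)), 1, tolerance = 1e-10)

  full <- reconstruct(pca, ncol(fm$values))
  expect_equal(full$values, fm$values, tolerance = 1e-8)

  rank1 <- reconstruct(pca, 1)
  centered <- rank1$values - rowMeans(fm$values)
  expect_equal(qr(centered)$rank, 1)

  expect_error(reconstruct(pca, 0), "must be an integer")
  expect_error(reconstruct(pca, ncol(fm$values) + 1), "must be an integer")

  # reconstruction error decreases with m and matches the best rank-m
  # approximation of the centered matrix (via an independent prcomp fit)
  x <- fm$values
  xc <- x - rowMeans(x)
  pr <- stats::prcomp(t(xc), center = FALSE)
  errs <- vapply(seq_len(ncol(x)), function(m) {
    rec <- reconstruct(pca, m)
    best <- t(pr$x[, 1:m, drop = FALSE] %*% t(pr$rotation[, 1:m, drop = FALSE]))
    expect_equal(norm(rec$values - rowMeans(x) - best, "F"), 0, tolerance = 1e-6)
    norm(rec$values - x, "F")
  }, numeric(1))
  expect_true(all(diff(errs) < 1e-8))
})

test_that("degenerate inputs: identical columns reconstruct to the mean with I_diff 0", {
  vals <- matrix(rep(stats::rnorm(20), 4), ncol = 4)
  fm <- idiffr:::new_feature_matrix(vals, c("s1", "s2"), "node_vector", 20, "c1", "strength")
  pca <- fit_pca(fm)
  expect_equal(reconstruct(pca, 2)$values, fm$values, tolerance = 1e-10)
  ident <- identifiability_matrix(fm)
  expect_equal(unname(ident$matrix), matrix(1, 2, 2))
  expect_equal(ident$I_diff, 0)

  # a zero-variance column makes the correlation undefined
  vals2 <- vals; vals2[, 2] <- 5
  fm2 <- idiffr:::new_feature_matrix(vals2, c("s1", "s2"), "node_vector", 20, "c1", "strength")
  expect_error(identifiability_matrix(fm2), "zero-variance")
})

test_that("identifiability matrix matches a hand-computed Pearson oracle (S = 3)", {
  set.seed(2)
  vals <- matrix(stats::rnorm(60), ncol = 6)
  fm <- idiffr:::new_feature_matrix(vals, c("a", "b", "c"), "node_vector", 10, "c1", NULL)
  ident <- identifiability_matrix(fm)
  for (i in 1:3) for (j in 1:3) {
    expect_equal(ident$matrix[i, j], stats::cor(vals[, i], vals[, 3 + j]))
  }
  expect_equal(ident$I_self, mean(diag(ident$matrix)))
  expect_equal(ident$I_diff,
               100 * (ident$I_self - mean(ident$matrix[row(ident$matrix) != col(ident$matrix)])))

  g <- glance(ident)
  expect_equal(g$I_diff, ident$I_diff)
  expect_equal(nrow(tidy(ident)), 9)
})

test_that("orthogonal subject fingerprints give I_self = 1 and I_diff near 100", {
  s <- 4; f <- 40
  base <- qr.Q(qr(matrix(stats::rnorm(f * s), f, s)))  # orthonormal columns
  vals <- cbind(base, base)                            # retest = test exactly
  fm <- idiffr:::new_feature_matrix(vals, sprintf("s%d", 1:s), "node_vector",
                                    f, "c1", NULL)
  ident <- identifiability_matrix(fm)
  expect_equal(ident$I_self, 1, tolerance = 1e-10)
  expect_lt(abs(ident$I_others), 0.35)   # near zero for orthogonalized features
  expect_gt(ident$I_diff, 65)
})

test_that("subject relabeling and test/retest swaps behave as symmetries", {
  co <- tiny_cohort(n_subjects = 4, n_nodes = 8, conditions = "c1", seed = 12)
  fm <- build_feature_matrix(co, "c1")
  ident <- identifiability_matrix(fm)

  s <- 4
  perm <- c(3, 1, 4, 2)
  fm_perm <- fm
  fm_perm$values <- fm$values[, c(perm, s + perm)]
  fm_perm$subjects <- fm$subjects[perm]
  ident_perm <- identifiability_matrix(fm_perm)
  expect_equal(unname(ident_perm$matrix), unname(ident$matrix[perm, perm]))
  expect_equal(ident_perm$I_diff, ident$I_diff)

  fm_swap <- fm
  fm_swap$values <- fm$values[, c(s + seq_len(s), seq_len(s))]
  ident_swap <- identifiability_matrix(fm_swap)
  expect_equal(unname(ident_swap$matrix), t(unname(ident$matrix)))
  expect_equal(ident_swap$I_self, ident$I_self)
  expect_equal(ident_swap$I_diff, ident$I_diff)
})

test_that("component sweep finds the optimum and validates its range", {
  co <- tiny_cohort(n_subjects = 4, n_nodes = 10, conditions = "c1", seed = 5)
  fm <- build_feature_matrix(co, "c1")
  prof <- sweep_components(fm)
  expect_equal(prof$m, 1:8)
  expect_true(all(diff(prof$R2) >= -1e-12))
  opt <- profile_optimum(prof)
  expect_equal(opt$I_diff_star, max(prof$I_diff))
  expect_equal(opt$m_star, min(prof$m[prof$I_diff == max(prof$I_diff)]))
  expect_equal(prof$I_diff[prof$m == 8], opt$I_diff_full, tolerance = 1e-6)

  single <- sweep_components(fm, m_range = 8)
  expect_equal(nrow(single), 1)
  expect_equal(profile_optimum(single)$m_star, 8)

  expect_error(sweep_components(fm, m_range = integer(0)), "empty")
  expect_error(sweep_components(fm, m_range = 0:3), "within")
  expect_error(sweep_components(fm, m_range = 9), "within")

  expect_equal(nrow(glance(prof)), 1)
  expect_s3_class(tidy(prof), "tbl_df")
})

test_that("a pure-noise cohort shows no fingerprint beyond the permutation null", {
  co <- generate_cohort(cohort_design(
    n_subjects = 6, cortical_nodes = 10, subcortical_nodes = 0, conditions = "c1",
    timeseries_length = 80, subject_signal = 0, condition_signal = 0,
    noise_signal = 1, seed = 21
  ))
  fm <- build_feature_matrix(co, "c1")
  ident <- identifiability_matrix(fm)
  set.seed(1)
  null <- idiff_permutation_null(ident, n_perm = 200)
  expect_lt(abs(ident$I_diff - mean(null)), 4 * stats::sd(null) + 1e-9)
})
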