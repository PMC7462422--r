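test_that("clamping replaces non-positive correlations and validates input", {
  fc <- matrix(c(1, -0.3, 0, -0.3, 1, 0.4, 0, 0.4, 1), 3, 3)
  g <- clamp_negative(fc)
  expect_equal(g$weights[1, 2], 2.220446049250313e-16)
  expect_equal(g$weights[1, 3], .Machine$double.eps)  # zero entries clamped too
  expect_equal(g$weights[2, 3], 0.4)                  # positives untouched
  expect_equal(diag(g$weights), rep(0, 3))
  expect_true(all(g$weights[row(g$weights) != col(g$weights)] > 0))

  asym <- fc; asym[1, 2] <- 0.9
  expect_error(clamp_negative(asym), "symmetric")
  expect_error(clamp_negative(fc, eps_clamp = 0), "positive")
  expect_error(clamp_negative(fc, eps_clamp = -1e-16), "positive")
})

test_that("degree strength sums edge weights", {
  tri <- matrix(1, 3, 3); diag(tri) <- 0
  expect_equal(strip_prop(degree_strength(clamp_negative(tri))), c(2, 2, 2))

  path <- matrix(0, 3, 3); path[1, 2] <- path[2, 3] <- 1; path <- path + t(path)
  # keep the missing edge truly absent for the hand-checked value
  g <- structure(list(weights = path, n = 3, eps_clamp = .Machine$double.eps),
                 class = "prepared_graph")
  expect_equal(strip_prop(degree_strength(g)), c(1, 2, 1))

  set.seed(1)
  w <- clamp_negative(rand_weighted_graph(6))$weights
  g6 <- structure(list(weights = w, n = 6, eps_clamp = .Machine$double.eps),
                  class = "prepared_graph")
  manual <- vapply(1:6, function(i) sum(w[i, -i]), numeric(1))
  expect_equal(strip_prop(degree_strength(g6)), manual)
})

test_that("hand-checked path examples: SPL, SI, betweenness, communicability, clustering", {
  # chain a-b-c with unit weights plus a weak direct a-c edge
  w <- matrix(0, 3, 3)
  w[1, 2] <- w[2, 3] <- 1; w[1, 3] <- 0.4
  w <- w + t(w); diag(w) <- 1
  g <- clamp_negative(w)
  spl <- shortest_path_length(g)
  expect_equal(spl[1, 3], 2)        # via b: 1 + 1 < 1/0.4
  expect_equal(spl[1, 2], 1)
  expect_true(all(diag(spl) == 0))
  expect_equal(strip_prop(spl), t(strip_prop(spl)))

  # unit chain: one bit to choose the correct exit at b
  chain <- matrix(0, 3, 3); chain[1, 2] <- chain[2, 3] <- 1
  chain <- chain + t(chain)
  gc2 <- structure(list(weights = chain, n = 3, eps_clamp = .Machine$double.eps),
                   class = "prepared_graph")
  si <- search_information(gc2)
  expect_equal(si[1, 3], 1)
  expect_equal(si[1, 2], 0)   # single exit from a: probability 1
  bc <- betweenness_centrality(gc2)
  expect_equal(strip_prop(bc), c(0, 1, 0))

  # two nodes, unit weight: communicability = sinh(1) off-diagonal
  two <- matrix(c(0, 1, 1, 0), 2, 2)
  g2 <- structure(list(weights = two, n = 2, eps_clamp = .Machine$double.eps),
                  class = "prepared_graph")
  expect_equal(communicability(g2)[1, 2], sinh(1), tolerance = 1e-12)
  expect_equal(search_information(g2)[1, 2], 0)

  # triangle with one weak edge: apex clustering = (1 * 1 * 0.125)^(1/3) / 1
  tri <- matrix(1, 3, 3); diag(tri) <- 0; tri[2, 3] <- tri[3, 2] <- 0.125
  gt <- structure(list(weights = tri, n = 3, eps_clamp = .Machine$double.eps),
                  class = "prepared_graph")
  expect_equal(strip_prop(clustering_coefficient(gt))[1], 0.5)
  full <- matrix(1, 3, 3); diag(full) <- 0
  gf <- structure(list(weights = full, n = 3, eps_clamp = .Machine$double.eps),
                  class = "prepared_graph")
  expect_equal(strip_prop(clustering_coefficient(gf)), c(1, 1, 1))
})

test_that("two-node closed forms: MFPT, driftness bound attained", {
  two <- matrix(c(0, 1, 1, 0), 2, 2)
  g2 <- structure(list(weights = two, n = 2, eps_clamp = .Machine$double.eps),
                  class = "prepared_graph")
  ms <- markov_structures(g2)
  expect_equal(ms$P, matrix(c(0, 1, 1, 0), 2, 2))
  expect_equal(ms$phi, c(0.5, 0.5))
  expect_equal(mean_first_passage_time(ms)[1, 2], 1)
  expect_equal(driftness(g2)[1, 2], 1)  # single-step walk is the shortest path
})

test_that("all measures agree with brute-force oracles on small random graphs", {
  set.seed(42)
  for (rep in 1:8) {
    n <- sample(4:7, 1)
    wc <- clamp_negative(rand_weighted_graph(n))$weights
    g <- structure(list(weights = wc, n = n, eps_clamp = .Machine$double.eps),
                   class = "prepared_graph")

    spl <- shortest_path_length(g)
    expect_identical(unname(strip_prop(spl)), oracle_spl(wc))

    expect_equal(strip_prop(betweenness_centrality(g)), oracle_betweenness(wc),
                 tolerance = 1e-12)

    expect_equal(strip_prop(search_information(g, spl = spl)), oracle_search_info(wc),
                 tolerance = 1e-10)

    ms <- markov_structures(g)
    expect_equal(rowSums(ms$P), rep(1, n), tolerance = 1e-12)
    expect_equal(as.vector(ms$phi %*% ms$P), ms$phi, tolerance = 1e-10)
    expect_equal(ms$phi, oracle_stationary_power(ms$P), tolerance = 1e-12)

    mfpt <- mean_first_passage_time(ms)
    expect_equal(strip_prop(mfpt), oracle_hitting(wc), tolerance = 1e-8)

    drift <- driftness(g, ms = ms, spl = spl)
    oracle_drift <- oracle_hitting(wc, cost_per_edge = TRUE) / strip_prop(spl)
    diag(oracle_drift) <- 0
    expect_equal(strip_prop(drift), unname(oracle_drift), tolerance = 1e-8)
    expect_true(min(drift[row(drift) != col(drift)]) >= 1 - 1e-12)

    expect_equal(strip_prop(communicability(g)), oracle_communicability(wc),
                 tolerance = 1e-10)
    expect_equal(strip_prop(clustering_coefficient(g)), oracle_clustering(wc),
                 tolerance = 1e-10)
  }
})

test_that("MFPT and journey time match Monte-Carlo walks within 3 standard errors", {
  set.seed(7)
  # complete graph: every edge is real, so the walk's expected journey cost is
  # reachable by simulation (clamped eps edges carry a tiny-probability,
  # huge-cost contribution that finite sampling cannot see)
  w <- clamp_negative(rand_weighted_graph(5, density = 1))$weights
  g <- structure(list(weights = w, n = 5, eps_clamp = .Machine$double.eps),
                 class = "prepared_graph")
  ms <- markov_structures(g)
  mfpt <- mean_first_passage_time(ms)
  mc <- oracle_walk_mc(w, 1, 4, 4000)
  expect_lt(abs(mfpt[1, 4] - mc["mean"]), 3 * mc["se"])
  h <- idiffr:::expected_journey_time(ms)
  mcj <- oracle_walk_mc(w, 1, 4, 4000, cost_per_edge = TRUE)
  expect_lt(abs(h[1, 4] - mcj["mean"]), 3 * mcj["se"])
})

test_that("network_properties returns the eight tagged measures and is pure and equivariant", {
  set.seed(5)
  co <- tiny_cohort(n_subjects = 2, n_nodes = 8, conditions = "c1")
  fc <- cohort_matrix(co, "sub001", "c1", "test")
  props <- network_properties(fc)
  expect_named(props, network_property_names())
  kinds <- vapply(props, attr, character(1), "kind")
  expect_equal(sum(kinds == "node"), 3)
  expect_equal(sum(kinds != "node"), 5)
  for (p in names(props)) {
    k <- kinds[[p]]
    if (k == "node") expect_length(props[[p]], 8)
    else expect_equal(dim(props[[p]]), c(8, 8))
    if (k == "pairwise_symmetric") {
      expect_equal(strip_prop(props[[p]]), t(strip_prop(props[[p]])))
    }
  }

  expect_identical(network_properties(fc), props)  # purity

  perm <- sample(8)
  props_p <- network_properties(fc[perm, perm])
  for (p in names(props)) {
    if (kinds[[p]] == "node") {
      expect_equal(strip_prop(props_p[[p]]), strip_prop(props[[p]])[perm],
                   tolerance = 1e-10)
    } else {
      expect_equal(strip_prop(props_p[[p]]), strip_prop(props[[p]])[perm, perm],
                   tolerance = 1e-10)
    }
  }

  expect_error(network_properties(fc, "modularity"), "spl")
})

test_that("properties can be written as per-run delimited files", {
  co <- tiny_cohort(n_subjects = 2, n_nodes = 6, conditions = "c1", seed = 13)
  props <- network_properties(cohort_matrix(co, "sub001", "c1", "test"),
                              c("spl", "strength"))
  dir <- withr::local_tempdir()
  out <- write_properties(props, dir, "sub001", "c1", "test")
  expect_true(all(file.exists(out$path)))
  expect_match(out$path[1], "sub001_c1_test_spl.csv")
  back <- as.matrix(utils::read.csv(out$path[out$property == "spl"], header = FALSE))
  expect_equal(unname(back), strip_prop(props$spl))
})
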