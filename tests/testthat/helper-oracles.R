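# Brute-force reference implementations, independent of the package's code
# paths: exhaustive path enumeration, per-target linear solves, Monte-Carlo
# walks, power series, triple loops, and aov-based ICC.

# random connected weighted graph as a symmetric weight matrix; zero entries
# mean "no measured edge" and are clamped to eps downstream
rand_weighted_graph <- function(n, density = 0.6) {
  repeat {
    a <- matrix(stats::runif(n * n) < density, n, n)
    a[lower.tri(a, diag = TRUE)] <- FALSE
    a <- a | t(a)
    g <- igraph::graph_from_adjacency_matrix(a, mode = "undirected")
    if (igraph::is_connected(g)) break
  }
  w <- matrix(0, n, n)
  w[upper.tri(w)] <- ifelse(a[upper.tri(a)], stats::runif(sum(upper.tri(a)), 0.05, 1), 0)
  w <- w + t(w)
  w
}

# FC-like input for the same graph: fill non-edges with negative values so
# clamp_negative() turns them into eps edges
as_fc_like <- function(w) {
  fc <- w
  fc[fc == 0] <- -0.5
  diag(fc) <- 1
  fc
}

# all simple paths i -> j over the strictly positive entries of w
enumerate_paths <- function(w, from, to) {
  n <- nrow(w)
  paths <- list()
  walk <- function(path) {
    last <- path[length(path)]
    if (last == to) {
      paths[[length(paths) + 1]] <<- path
      return(invisible())
    }
    for (nxt in seq_len(n)) {
      if (w[last, nxt] > 0 && !(nxt %in% path)) walk(c(path, nxt))
    }
  }
  walk(from)
  paths
}

path_length <- function(w, path) {
  # left-to-right accumulation, matching Dijkstra's order of additions
  len <- 0
  for (k in seq_len(length(path) - 1)) len <- len + 1 / w[path[k], path[k + 1]]
  len
}

oracle_spl <- function(w) {
  n <- nrow(w)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    d[i, j] <- min(vapply(enumerate_paths(w, i, j), function(p) path_length(w, p),
                          numeric(1)))
  }
  d
}

shortest_paths_between <- function(w, i, j) {
  ps <- enumerate_paths(w, i, j)
  lens <- vapply(ps, function(p) path_length(w, p), numeric(1))
  ps[lens == min(lens)]
}

oracle_betweenness <- function(w) {
  n <- nrow(w)
  b <- numeric(n)
  for (h in seq_len(n)) for (j in seq_len(n)) {
    if (h == j) next
    sp <- shortest_paths_between(w, h, j)
    rho <- length(sp)
    for (i in seq_len(n)) {
      if (i == h || i == j) next
      through <- sum(vapply(sp, function(p) i %in% p, logical(1)))
      b[i] <- b[i] + through / rho
    }
  }
  b / ((n - 1) * (n - 2))
}

oracle_search_info <- function(w) {
  n <- nrow(w)
  k <- rowSums(w)
  si <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    prob <- 0
    for (p in shortest_paths_between(w, i, j)) {
      pr <- 1
      for (l in seq_len(length(p) - 1)) pr <- pr * w[p[l], p[l + 1]] / k[p[l]]
      prob <- prob + pr
    }
    si[i, j] <- -log2(prob)
  }
  si
}

# hitting times from per-target linear systems; costs = 1 gives step MFPT,
# costs = 1/w gives the journey time used by driftness
oracle_hitting <- function(w, cost_per_edge = FALSE) {
  n <- nrow(w)
  p <- w / rowSums(w)
  r <- if (cost_per_edge) rowSums(p * ifelse(w > 0, 1 / w, 0)) else rep(1, n)
  h <- matrix(0, n, n)
  for (j in seq_len(n)) {
    keep <- setdiff(seq_len(n), j)
    sol <- solve(diag(n - 1) - p[keep, keep, drop = FALSE], r[keep])
    h[keep, j] <- sol
  }
  h
}

oracle_walk_mc <- function(w, from, to, n_walks, cost_per_edge = FALSE) {
  p <- w / rowSums(w)
  n <- nrow(w)
  vals <- vapply(seq_len(n_walks), function(its) {
    node <- from
    acc <- 0
    while (node != to) {
      nxt <- sample.int(n, 1, prob = p[node, ])
      acc <- acc + if (cost_per_edge) 1 / w[node, nxt] else 1
      node <- nxt
    }
    acc
  }, numeric(1))
  c(mean = mean(vals), se = stats::sd(vals) / sqrt(n_walks))
}

oracle_communicability <- function(w, tol = 1e-13) {
  k <- rowSums(w)
  m <- w / sqrt(outer(k, k))
  acc <- diag(nrow(w))
  term <- diag(nrow(w))
  for (i in 1:200) {
    term <- term %*% m / i
    acc <- acc + term
    if (max(abs(term)) < tol) break
  }
  acc
}

oracle_clustering <- function(w) {
  n <- nrow(w)
  cc <- numeric(n)
  for (i in seq_len(n)) {
    ti <- 0
    for (j in seq_len(n)) for (h in seq_len(n)) {
      if (j == i || h == i || j == h) next
      ti <- ti + (w[i, j] * w[i, h] * w[j, h])^(1 / 3)
    }
    ti <- ti / 2
    ki <- sum(w[i, ] > 0)
    cc[i] <- if (ki < 2) 0 else 2 * ti / (ki * (ki - 1))
  }
  cc
}

oracle_stationary_power <- function(p, tol = 1e-15, max_iter = 200000) {
  # iterate the lazy chain (I + P)/2: same stationary distribution, but a
  # nonnegative spectrum, so bipartite-like graphs cannot make it oscillate
  lazy <- (diag(nrow(p)) + p) / 2
  phi <- rep(1 / nrow(p), nrow(p))
  for (i in seq_len(max_iter)) {
    nxt <- as.vector(phi %*% lazy)
    nxt <- nxt / sum(nxt)
    if (max(abs(nxt - phi)) < tol) return(nxt)
    phi <- nxt
  }
  phi
}

oracle_icc_aov <- function(groups) {
  y <- unlist(groups)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  k <- length(groups[[1]])
  tab <- stats::anova(stats::aov(y ~ g))
  msb <- tab["g", "Mean Sq"]
  msw <- tab["Residuals", "Mean Sq"]
  (msb - msw) / (msb + (k - 1) * msw)
}

# drop the property/kind tags so results compare cleanly against oracles
strip_prop <- function(x) {
  a <- attributes(x)
  attributes(x) <- if (!is.null(a$dim)) list(dim = a$dim) else NULL
  x
}

# small synthetic cohort shared by several test files
tiny_cohort <- function(n_subjects = 4, n_nodes = 10, conditions = c("c1", "c2"),
                        tt = 120, a = 0.6, b = 0.2, cc = 0.4, seed = 11) {
  generate_cohort(cohort_design(
    n_subjects = n_subjects, cortical_nodes = n_nodes, subcortical_nodes = 0,
    conditions = conditions, timeseries_length = tt,
    subject_signal = a, condition_signal = b, noise_signal = cc, seed = seed
  ))
}

new_cohort_for_tests <- function() {
  idiffr:::new_cohort(
    list(),
    tibble::tibble(subject_id = character(), condition = character(), run = character()),
    0L, NULL
  )
}
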