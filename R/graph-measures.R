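#' Clamp non-positive correlations and prepare a connectome as a graph
#'
#' Replaces every non-positive off-diagonal entry of a symmetric correlation
#' matrix by a small positive constant (machine epsilon by default) and drops
#' the diagonal.  Clamping zeros as well as negatives makes the weighted graph
#' complete, hence connected, and its random-walk Markov chain regular — the
#' two properties the passage-time computations require.
#'
#' @param fc Symmetric correlation matrix (or an already prepared graph,
#'   returned unchanged).
#' @param eps_clamp Positive replacement constant; defaults to
#'   [eps_clamp_default()].
#' @param tol Symmetry tolerance on the input.
#' @return A `prepared_graph`: list with `weights` (exactly symmetric, zero
#'   diagonal, strictly positive off-diagonal), `n`, and `eps_clamp`.
#' @export
clamp_negative <- function(fc, eps_clamp = eps_clamp_default(), tol = 1e-8) {
  if (inherits(fc, "prepared_graph")) return(fc)
  if (!is.matrix(fc) || nrow(fc) != ncol(fc)) abort("`fc` must be a square matrix.")
  if (!is.numeric(eps_clamp) || length(eps_clamp) != 1 || eps_clamp <= 0) {
    abort("`eps_clamp` must be a single positive number.")
  }
  if (max(abs(fc - t(fc))) > tol) abort("`fc` must be symmetric.")
  w <- (fc + t(fc)) / 2
  mask <- w <= 0
  diag(mask) <- FALSE
  w[mask] <- eps_clamp
  diag(w) <- 0
  structure(list(weights = w, n = nrow(w), eps_clamp = eps_clamp),
            class = "prepared_graph")
}

#' @export
print.prepared_graph <- function(x, ...) {
  cat(sprintf("<prepared_graph> %d nodes, complete weighted graph (eps = %.3g)\n",
              x$n, x$eps_clamp))
  invisible(x)
}

new_property <- function(values, property, kind) {
  structure(values, property = property, kind = kind, class = NULL)
}

igraph_of <- function(g) {
  igraph::graph_from_adjacency_matrix(g$weights, mode = "undirected",
                                      weighted = TRUE, diag = FALSE)
}

#' Degree strength
#'
#' Weighted sum of the edges attached to each node, `K_i = sum_j w_ij`.
#'
#' @param g A `prepared_graph` (or a matrix passed through [clamp_negative()]).
#' @param eps_clamp Clamping constant used when `g` is a raw matrix.
#' @return Length-n numeric vector.
#' @export
degree_strength <- function(g, eps_clamp = eps_clamp_default()) {
  g <- clamp_negative(g, eps_clamp)
  new_property(rowSums(g$weights), "strength", "node")
}

#' Weighted shortest path lengths
#'
#' Edge lengths are inverse weights, so the shortest path between two nodes
#' minimises `sum(1/w)` along the path (strong correlations are short hops).
#'
#' @inheritParams degree_strength
#' @return Symmetric n x n matrix of path lengths, zero diagonal.
#' @export
shortest_path_length <- function(g, eps_clamp = eps_clamp_default()) {
  g <- clamp_negative(g, eps_clamp)
  ig <- igraph_of(g)
  d <- igraph::distances(ig, weights = 1 / igraph::E(ig)$weight, algorithm = "dijkstra")
  dimnames(d) <- NULL
  new_property(d, "spl", "pairwise_symmetric")
}

#' Search information
#'
#' Bits needed to steer an unbiased random walker along the shortest path from
#' i to j: `SI_ij = -log2 P(pi_i->j)`, where the path probability is the
#' product, over every node l on the path except the target, of the weighted
#' transition probability `w_(l,next) / K_l`.  If several shortest paths tie
#' exactly, their probabilities are summed before taking the logarithm.
#' `SI_ij != SI_ji` in general.
#'
#' @inheritParams degree_strength
#' @param spl Optional precomputed [shortest_path_length()] matrix.
#' @return n x n matrix (asymmetric), zero diagonal.
#' @export
search_information <- function(g, eps_clamp = eps_clamp_default(), spl = NULL) {
  g <- clamp_negative(g, eps_clamp)
  n <- g$n
  w <- g$weights
  if (is.null(spl)) spl <- shortest_path_length(g)
  len <- 1 / w          # edge lengths; Inf on the (zero) diagonal
  p <- w / rowSums(w)   # transition probabilities
  si <- matrix(0, n, n)
  for (i in seq_len(n)) {
    d <- spl[i, ]
    ord <- order(d)
    q <- numeric(n)
    q[i] <- 1
    # accumulate path probabilities over the shortest-path DAG in distance
    # order; predecessor detection uses exact equality (ties have measure
    # zero for correlation weights)
    for (v in ord[-1]) {
      pred <- which(d + len[, v] == d[v])
      q[v] <- sum(q[pred] * p[pred, v])
    }
    si[i, ] <- -log2(q)
    si[i, i] <- 0
  }
  new_property(si, "search_info", "pairwise_asymmetric")
}

#' Random-walk structures of a prepared graph
#'
#' The transition matrix `P = W / K`, the stationary distribution `phi`
#' (`phi_i = K_i / sum(K)` for this reversible chain, i.e. the left
#' eigenvector of P at eigenvalue 1), and the Kemeny-Snell fundamental matrix
#' `Z = (I - P + Phi)^-1`, where `Phi` has every row equal to `phi`.
#'
#' @inheritParams degree_strength
#' @return A `markov_structures` list with elements `P`, `phi`, `Z`, `Phi`.
#' @export
markov_structures <- function(g, eps_clamp = eps_clamp_default()) {
  g <- clamp_negative(g, eps_clamp)
  n <- g$n
  k <- rowSums(g$weights)
  p <- g$weights / k
  phi <- k / sum(k)
  bigphi <- matrix(phi, n, n, byrow = TRUE)
  a <- diag(n) - p + bigphi
  z <- tryCatch(solve(a), error = function(e) {
    abort(sprintf(
      "Fundamental-matrix solve failed (reciprocal condition number %.3g): %s",
      rcond(a), conditionMessage(e)
    ))
  })
  structure(list(P = p, phi = phi, Z = z, Phi = bigphi, n = n, weights = g$weights),
            class = "markov_structures")
}

#' Mean first passage time
#'
#' Expected number of steps for the weighted random walker to first reach j
#' from i, via the fundamental matrix:
#' `MFPT_ij = (zeta_jj - zeta_ij) / phi_j`.
#'
#' @param ms A [markov_structures()] object, or a graph/matrix from which one
#'   is built.
#' @param eps_clamp Clamping constant used when building from a raw matrix.
#' @return n x n matrix (asymmetric), zero diagonal, positive off-diagonal.
#' @export
mean_first_passage_time <- function(ms, eps_clamp = eps_clamp_default()) {
  if (!inherits(ms, "markov_structures")) ms <- markov_structures(ms, eps_clamp)
  n <- ms$n
  zd <- matrix(diag(ms$Z), n, n, byrow = TRUE)
  m <- (zd - ms$Z) / ms$Phi
  diag(m) <- 0
  new_property(m, "mfpt", "pairwise_asymmetric")
}

# Expected accumulated travel length (sum of 1/w over traversed edges) before
# the walker first hits each target.  With per-step cost r_i = sum_k P_ik/w_ik
# the hitting cost solves the same fundamental-matrix identity as MFPT:
#   H_ij = (zeta_jj - zeta_ij) * rbar / phi_j + u_i - u_j,  u = Z r, rbar = phi'r
# (reduces to MFPT when all costs are 1).
expected_journey_time <- function(ms) {
  n <- ms$n
  len <- 1 / ms$weights
  diag(len) <- 0
  r <- rowSums(ms$P * len)
  u <- as.vector(ms$Z %*% r)
  rbar <- sum(ms$phi * r)
  zd <- matrix(diag(ms$Z), n, n, byrow = TRUE)
  h <- (zd - ms$Z) * rbar / ms$Phi + matrix(u, n, n) - matrix(u, n, n, byrow = TRUE)
  diag(h) <- 0
  h
}

#' Driftness
#'
#' Ratio of the random walker's expected journey time to the shortest path
#' length between i and j, both measured in inverse-weight length units.  The
#' shortest path is the best possible route for the walker, so
#' `W_ij >= 1` always, with 1 meaning the walk drifts no slower than the
#' optimal route.
#'
#' @inheritParams degree_strength
#' @param ms,spl Optional precomputed [markov_structures()] and
#'   [shortest_path_length()] results.
#' @return n x n matrix (asymmetric), zero diagonal, off-diagonal >= 1.
#' @export
driftness <- function(g, eps_clamp = eps_clamp_default(), ms = NULL, spl = NULL) {
  g <- clamp_negative(g, eps_clamp)
  if (is.null(ms)) ms <- markov_structures(g)
  if (is.null(spl)) spl <- shortest_path_length(g)
  if (!all(dim(spl) == c(g$n, g$n))) abort("`spl` dimensions do not match the graph.")
  h <- expected_journey_time(ms)
  w <- h / spl
  diag(w) <- 0
  new_property(w, "driftness", "pairwise_asymmetric")
}

#' Normalized communicability
#'
#' Weighted count of all walks between node pairs, with hub influence tamed by
#' degree normalization: `C = expm(D^-1/2 A D^-1/2)` with `D = diag(K)`.
#'
#' @inheritParams degree_strength
#' @return Symmetric n x n matrix.
#' @export
communicability <- function(g, eps_clamp = eps_clamp_default()) {
  g <- clamp_negative(g, eps_clamp)
  k <- rowSums(g$weights)
  m <- g$weights / sqrt(outer(k, k))
  cm <- as.matrix(Matrix::expm(Matrix::Matrix(m, sparse = FALSE)))
  cm <- (cm + t(cm)) / 2
  dimnames(cm) <- NULL
  new_property(cm, "communicability", "pairwise_symmetric")
}

#' Weighted clustering coefficient
#'
#' Onnela's weighted form: the triangle intensity around node i is
#' `t_i = 1/2 sum_(j,h) (w_ij w_ih w_jh)^(1/3)` and
#' `CC_i = 2 t_i / (k_i (k_i - 1))` with `k_i` the binary degree (number of
#' positive-weight neighbours).  With correlation weights (<= 1) the result
#' lies in \[0, 1\]; nodes with fewer than two neighbours get 0.
#'
#' @inheritParams degree_strength
#' @return Length-n numeric vector.
#' @export
clustering_coefficient <- function(g, eps_clamp = eps_clamp_default()) {
  g <- clamp_negative(g, eps_clamp)
  if (g$n < 3) abort("Clustering needs at least 3 nodes.")
  w3 <- g$weights^(1 / 3)
  t3 <- diag(w3 %*% w3 %*% w3) / 2
  k <- rowSums(g$weights > 0)
  cc <- ifelse(k < 2, 0, 2 * t3 / (k * (k - 1)))
  new_property(cc, "clustering", "node")
}

#' Betweenness centrality
#'
#' Fraction of weighted shortest paths (lengths `1/w`) between other node
#' pairs that pass through each node, normalized by `(n-1)(n-2)` ordered
#' pairs so values lie in \[0, 1\].
#'
#' @inheritParams degree_strength
#' @return Length-n numeric vector.
#' @export
betweenness_centrality <- function(g, eps_clamp = eps_clamp_default()) {
  g <- clamp_negative(g, eps_clamp)
  if (g$n < 3) abort("Betweenness needs at least 3 nodes.")
  ig <- igraph_of(g)
  b <- igraph::betweenness(ig, weights = 1 / igraph::E(ig)$weight, normalized = TRUE)
  new_property(unname(b), "betweenness", "node")
}

#' Compute network properties of one connectome
#'
#' Clamps once, then evaluates the requested measures, sharing the shortest
#' path and random-walk structures across measures that need them.
#'
#' @param fc Symmetric connectome matrix or `prepared_graph`.
#' @param properties Character vector of property names, see
#'   [network_property_names()]; defaults to all eight.
#' @param eps_clamp Clamping constant for non-positive correlations.
#' @return Named list of property arrays, each carrying attributes `property`
#'   and `kind` (`node`, `pairwise_symmetric` or `pairwise_asymmetric`).
#' @examples
#' fc <- diag(4)
#' fc[upper.tri(fc)] <- c(0.5, 0.3, -0.2, 0.6, 0.4, 0.1)
#' fc <- fc + t(fc) - diag(diag(fc))
#' diag(fc) <- 1
#' props <- network_properties(fc)
#' names(props)
#' @export
network_properties <- function(fc, properties = network_property_names(),
                               eps_clamp = eps_clamp_default()) {
  check_property_names(properties)
  g <- clamp_negative(fc, eps_clamp)
  out <- list()
  spl <- NULL
  ms <- NULL
  need_spl <- any(c("spl", "search_info", "driftness") %in% properties)
  need_ms <- any(c("mfpt", "driftness") %in% properties)
  if (need_spl) spl <- shortest_path_length(g)
  if (need_ms) ms <- markov_structures(g)
  for (p in properties) {
    out[[p]] <- switch(p,
      strength        = degree_strength(g),
      spl             = spl,
      search_info     = search_information(g, spl = spl),
      mfpt            = mean_first_passage_time(ms),
      driftness       = driftness(g, ms = ms, spl = spl),
      communicability = communicability(g),
      clustering      = clustering_coefficient(g),
      betweenness     = betweenness_centrality(g)
    )
  }
  out
}

#' Write computed network properties to delimited files
#'
#' One file per property, named `<subject>_<condition>_<run>_<property>.csv`:
#' full matrices for pairwise properties, a single column for node
#' properties.
#'
#' @param props Result of [network_properties()].
#' @param dir Output directory (created if needed).
#' @param subject_id,condition,run Identifiers used in the file names.
#' @return Tibble with columns `property`, `path`, invisibly.
#' @export
write_properties <- function(props, dir, subject_id, condition, run) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(names(props), function(p) {
    path <- file.path(dir, sprintf("%s_%s_%s_%s.csv", subject_id, condition, run, p))
    v <- props[[p]]
    m <- if (is.matrix(v)) v else matrix(as.numeric(v), ncol = 1)
    writeLines(apply(m, 1, function(r) paste(sprintf("%.17g", r), collapse = ",")),
               path)
    path
  }, character(1))
  invisible(tibble(property = names(props), path = unname(paths)))
}
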