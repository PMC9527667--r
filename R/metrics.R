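# Weighted graph statistics for symmetric nonnegative connectivity matrices.
# All functions take an N x N symmetric matrix with zero diagonal and
# nonnegative entries (a rectified correlation network) and return a scalar.

.check_adjacency <- function(A, min_n = 2L) {
  if (!is.matrix(A) || !is.numeric(A)) stop("adjacency must be a numeric matrix")
  n <- nrow(A)
  if (ncol(A) != n) stop("adjacency must be square")
  if (n < min_n) stop("adjacency must have at least ", min_n, " nodes")
  if (any(is.na(A))) stop("adjacency must not contain NA")
  if (any(A < 0)) stop("adjacency must be nonnegative; rectify the series first")
  if (max(abs(A - t(A))) > 1e-10) stop("adjacency must be symmetric")
  if (any(diag(A) != 0)) stop("adjacency must have a zero diagonal")
  invisible(n)
}

#' Weighted network density
#'
#' Total edge weight divided by the number of possible edges, `N(N-1)/2`.
#' For rectified correlation weights in `[0, 1]` the density is 1 for a
#' fully connected unit-weight network and 0 for an empty one.
#'
#' @param A Symmetric nonnegative adjacency matrix with zero diagonal.
#' @return Density in `[0, 1]` for weights bounded by 1.
#' @export
#' @examples
#' A <- matrix(1, 4, 4); diag(A) <- 0
#' network_density(A)  # 1
network_density <- function(A) {
  n <- .check_adjacency(A)
  sum(A[upper.tri(A)]) / (n * (n - 1) / 2)
}

#' Weighted clustering coefficient
#'
#' Mean over nodes of the Onnela cube-root triangle intensity
#' `C_i = sum_{jh} (A_ij A_ih A_jh)^(1/3) / (k_i (k_i - 1))`, where `k_i` is
#' the binary degree (number of nonzero links). Nodes with fewer than two
#' links contribute 0. Weights are used as-is (they are already bounded in
#' `[0, 1]` for rectified correlations), so the value of a unit-weight
#' clique is 1.
#'
#' @inheritParams network_density
#' @return Mean clustering coefficient.
#' @export
clustering_coefficient <- function(A) {
  n <- .check_adjacency(A, min_n = 3L)
  W <- A^(1 / 3)
  cyc3 <- diag(W %*% W %*% W)        # 2 * weighted triangles around each node
  k <- rowSums(A > 0)
  C <- numeric(n)
  ok <- k >= 2
  C[ok] <- cyc3[ok] / (k[ok] * (k[ok] - 1))
  mean(C)
}

#' Weighted characteristic path length
#'
#' Edge lengths are inverse weights (`l = 1/w`; strong links are short).
#' Returns the mean of all finite off-diagonal shortest-path distances.
#' Disconnected node pairs are excluded from the average; their count is
#' attached as attribute `n_excluded`. A graph with no finite pair returns
#' `NA` with a warning (the undefined-result marker).
#'
#' @inheritParams network_density
#' @return Mean shortest path length (possibly `NA`), with attribute
#'   `n_excluded` giving the number of unordered disconnected pairs.
#' @export
characteristic_path_length <- function(A) {
  n <- .check_adjacency(A)
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  if (igraph::ecount(g) == 0) {
    warning("no edges: characteristic path length undefined")
    return(structure(NA_real_, n_excluded = n * (n - 1) / 2))
  }
  D <- igraph::distances(g, weights = 1 / igraph::E(g)$weight)
  d <- D[upper.tri(D)]
  finite <- is.finite(d)
  if (!any(finite)) {
    warning("graph fully disconnected: characteristic path length undefined")
    return(structure(NA_real_, n_excluded = length(d)))
  }
  structure(mean(d[finite]), n_excluded = sum(!finite))
}

#' Weighted assortativity coefficient
#'
#' Pearson correlation of node strengths at the two endpoints of every
#' edge, each undirected edge counted in both orientations (the symmetric
#' formula used by weighted assortativity in standard connectivity
#' toolboxes). Negative values indicate that hubs preferentially attach to
#' low-strength nodes.
#'
#' @inheritParams network_density
#' @return Assortativity in `[-1, 1]`, or `NA` when the endpoint-strength
#'   variance is degenerate (e.g. a regular graph).
#' @export
assortativity_coef <- function(A) {
  .check_adjacency(A)
  s <- rowSums(A)
  idx <- which(upper.tri(A) & A > 0, arr.ind = TRUE)
  if (nrow(idx) < 2) {
    warning("fewer than 2 edges: assortativity undefined")
    return(NA_real_)
  }
  x <- c(s[idx[, 1]], s[idx[, 2]])
  y <- c(s[idx[, 2]], s[idx[, 1]])
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("degenerate endpoint-strength variance: assortativity undefined")
    return(NA_real_)
  }
  stats::cor(x, y)
}

#' Spectral radius
#'
#' Largest eigenvalue of the (symmetric) connectivity matrix; for a
#' nonnegative symmetric matrix this is real and nonnegative
#' (Perron-Frobenius) and indexes how easily activity spreads through the
#' network.
#'
#' @inheritParams network_density
#' @return Largest eigenvalue of `A`.
#' @export
spectral_radius <- function(A) {
  .check_adjacency(A, min_n = 1L)
  max(eigen(A, symmetric = TRUE, only.values = TRUE)$values)
}

#' Laplacian synchronizability
#'
#' `S = lambda_2(L) / lambda_max(L)` with `L = D - A` and `D` the diagonal
#' matrix of node strengths. S lies in `[0, 1]`; a disconnected graph has
#' `lambda_2 = 0` and hence `S = 0`; the complete unit-weight graph attains
#' the maximum `S = 1`.
#'
#' @inheritParams network_density
#' @return Eigenratio of the graph Laplacian.
#' @export
synchronizability <- function(A) {
  n <- .check_adjacency(A)
  if (sum(A) <= 0) stop("zero-weight graph: synchronizability undefined")
  L <- diag(rowSums(A)) - A
  ev <- sort(eigen(L, symmetric = TRUE, only.values = TRUE)$values)
  lambda2 <- max(ev[2L], 0)          # clamp eigen-solver roundoff
  lambda2 / ev[n]
}

#' Newman spectral modularity
#'
#' Community detection by the leading eigenvector of the modularity matrix
#' `B = A - gamma * k k' / 2m` with recursive bisection and a
#' Kernighan-Lin-style single-node fine-tuning sweep, stopping when no
#' split increases the modularity contribution. `k` is the weighted degree
#' (node strength) and `2m` the total weight, so the method operates on the
#' weighted matrix directly. The returned Q is evaluated with
#' `Q = 1/2m * sum_ij (A_ij - gamma k_i k_j / 2m) delta(c_i, c_j)`.
#'
#' Determinism: eigenvector entries within 1e-12 of zero are assigned to
#' the positive group, and the fine-tuning sweep visits nodes in index
#' order, breaking ties by the smallest index.
#'
#' @inheritParams network_density
#' @param gamma Resolution parameter (default 1).
#' @return List with `Q` (modularity of the returned partition) and
#'   `membership` (integer community labels, 1-based).
#' @export
network_modularity <- function(A, gamma = 1) {
  n <- .check_adjacency(A)
  m2 <- sum(A)
  if (m2 <= 0) stop("zero-weight graph: modularity undefined")
  k <- rowSums(A)
  B <- A - gamma * outer(k, k) / m2

  membership <- integer(n)
  next_label <- 1L
  queue <- list(seq_len(n))
  while (length(queue)) {
    g <- queue[[1L]]; queue <- queue[-1L]
    s <- .spectral_bisect(B, g)
    if (is.null(s)) {                 # indivisible
      membership[g] <- next_label
      next_label <- next_label + 1L
    } else {
      queue <- c(queue, list(g[s > 0], g[s < 0]))
    }
  }
  same <- outer(membership, membership, "==")
  Q <- sum(B * same) / m2
  list(Q = Q, membership = membership)
}

# Attempt to split node set g using the generalized modularity matrix
# B^(g)_ij = B_ij - delta_ij sum_{l in g} B_il. Returns a +/-1 vector over
# g, or NULL if the group is indivisible (split does not increase Q).
.spectral_bisect <- function(B, g) {
  if (length(g) < 2L) return(NULL)
  Bg <- B[g, g, drop = FALSE]
  Bg <- Bg - diag(rowSums(Bg), length(g))
  es <- eigen(Bg, symmetric = TRUE)
  v <- es$vectors[, 1L]
  if (es$values[1L] <= 1e-12) return(NULL)
  s <- ifelse(v >= -1e-12, 1, -1)    # zero-ish entries -> positive group
  s <- .kl_fine_tune(Bg, s)
  if (all(s > 0) || all(s < 0)) return(NULL)
  dQ <- drop(t(s) %*% Bg %*% s)
  if (dQ <= 1e-12) return(NULL)
  s
}

# Kernighan-Lin-style fine tuning: repeatedly sweep over nodes, each node
# moved at most once per sweep, keeping the best intermediate state; stop
# when a full sweep yields no improvement. Deterministic: candidate moves
# are scored together and ties go to the smallest node index.
.kl_fine_tune <- function(Bg, s) {
  n <- length(s)
  q <- drop(t(s) %*% Bg %*% s)
  repeat {
    s_try <- s
    q_try <- q
    free <- rep(TRUE, n)
    best_s <- s; best_q <- q
    for (step in seq_len(n)) {
      # gain of flipping node i: -4 s_i (Bg s)_i + 4 Bg_ii
      bs <- drop(Bg %*% s_try)
      gain <- -4 * s_try * bs + 4 * diag(Bg)
      gain[!free] <- -Inf
      i <- which.max(gain)            # ties: smallest index
      s_try[i] <- -s_try[i]
      free[i] <- FALSE
      q_try <- q_try + gain[i]
      if (q_try > best_q + 1e-12) { best_q <- q_try; best_s <- s_try }
    }
    if (best_q > q + 1e-12) { s <- best_s; q <- best_q } else break
  }
  s
}

#' All seven graph statistics of one network
#'
#' Convenience wrapper evaluating density, clustering coefficient,
#' characteristic path length, assortativity, modularity Q, spectral radius
#' and synchronizability on a single matrix. Undefined results come back as
#' `NA` rather than errors so that degenerate windows propagate as markers
#' through a metric time series.
#'
#' @inheritParams network_modularity
#' @return Named numeric vector of length 7.
#' @export
graph_metrics <- function(A, gamma = 1) {
  .check_adjacency(A)
  empty <- sum(A) <= 0
  c(density = network_density(A),
    clustering = if (nrow(A) >= 3) clustering_coefficient(A) else NA_real_,
    path_length = suppressWarnings(as.numeric(characteristic_path_length(A))),
    assortativity = suppressWarnings(assortativity_coef(A)),
    modularity = if (empty) NA_real_ else network_modularity(A, gamma)$Q,
    spectral_radius = spectral_radius(A),
    synchronizability = if (empty) NA_real_ else synchronizability(A))
}

#' Metric time series of a connectivity series
#'
#' Evaluates all seven graph statistics on every (rectified) smoothed
#' connectivity matrix of a segment. Undefined values (disconnected or
#' degenerate windows) are propagated as `NA` markers, never dropped.
#'
#' @param series A `connectivity_series` at stage `"rectified"`.
#' @param gamma Modularity resolution parameter.
#' @return Data frame with one row per smoothed window: `window_start`
#'   (seconds from segment start), `time_min` (minutes relative to onset)
#'   and one column per metric; attributes `segment_id` and `condition`
#'   carry over from the series.
#' @export
metric_timeseries <- function(series, gamma = 1) {
  stopifnot(inherits(series, "connectivity_series"))
  if (!identical(series$stage, "rectified"))
    stop("metric_timeseries requires a rectified connectivity series")
  W <- dim(series$matrices)[3L]
  vals <- t(vapply(seq_len(W),
                   function(w) graph_metrics(series$matrices[, , w], gamma),
                   numeric(7)))
  onset <- if (is.null(series$onset_time)) 0 else series$onset_time
  out <- data.frame(window_start = series$window_starts,
                    time_min = (series$window_starts - onset) / 60,
                    vals)
  attr(out, "segment_id") <- series$segment_id
  attr(out, "condition") <- series$condition
  out
}

#' The seven metric names, in canonical order
#' @rdname metric_timeseries
#' @format NULL
#' @export
metric_names <- c("density", "clustering", "path_length", "assortativity",
                  "modularity", "spectral_radius", "synchronizability")
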