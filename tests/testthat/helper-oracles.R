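# Independent brute-force oracles for the seven graph statistics. These
# deliberately use naive loops / direct formula evaluation so that they
# share no code path with the package implementations.

oracle_density <- function(A) {
  n <- nrow(A)
  tot <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) tot <- tot + A[i, j]
  tot / (n * (n - 1) / 2)
}

oracle_clustering <- function(A) {
  n <- nrow(A)
  C <- numeric(n)
  for (i in seq_len(n)) {
    k <- sum(A[i, ] > 0)
    if (k < 2) next
    s <- 0
    for (j in seq_len(n)) for (h in seq_len(n)) {
      if (j != i && h != i && j != h)
        s <- s + (A[i, j] * A[i, h] * A[j, h])^(1 / 3)
    }
    C[i] <- s / (k * (k - 1))
  }
  mean(C)
}

# Floyd-Warshall on lengths 1/w; mean of finite off-diagonal distances
oracle_cpl <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  for (i in seq_len(n)) for (j in seq_len(n))
    if (i != j && A[i, j] > 0) D[i, j] <- 1 / A[i, j]
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  d <- D[upper.tri(D)]
  if (!any(is.finite(d))) return(NA_real_)
  mean(d[is.finite(d)])
}

oracle_assortativity <- function(A) {
  n <- nrow(A)
  s <- rowSums(A)
  x <- c(); y <- c()
  for (i in seq_len(n)) for (j in seq_len(n))
    if (i != j && A[i, j] > 0) { x <- c(x, s[i]); y <- c(y, s[j]) }
  if (length(x) < 4 || stats::sd(x) == 0) return(NA_real_)
  stats::cor(x, y)
}

oracle_spectral_radius <- function(A) {
  max(Re(eigen(A)$values))
}

oracle_synchronizability <- function(A) {
  n <- nrow(A)
  L <- diag(rowSums(A)) - A
  ev <- sort(Re(eigen(L)$values))
  max(ev[2], 0) / ev[n]
}

# Q of a given partition evaluated with the printed equation (weighted
# degree k, 2m = total weight), by direct double loop
oracle_modularity_Q <- function(A, membership, gamma = 1) {
  n <- nrow(A)
  m2 <- sum(A)
  k <- rowSums(A)
  q <- 0
  for (i in seq_len(n)) for (j in seq_len(n))
    if (membership[i] == membership[j])
      q <- q + A[i, j] - gamma * k[i] * k[j] / m2
  q / m2
}

# all symmetric zero-diagonal matrices on n nodes with weights from ws
enumerate_graphs <- function(n, ws = c(0, 0.3, 1)) {
  n_edges <- n * (n - 1) / 2
  grid <- as.matrix(expand.grid(rep(list(ws), n_edges)))
  lapply(seq_len(nrow(grid)), function(r) {
    A <- matrix(0, n, n)
    A[upper.tri(A)] <- grid[r, ]
    A + t(A)
  })
}

random_graph <- function(n, ws = c(0, 0.3, 1)) {
  A <- matrix(0, n, n)
  A[upper.tri(A)] <- sample(ws, n * (n - 1) / 2, replace = TRUE)
  A + t(A)
}

# compare implementation vs oracles on one matrix; returns max abs error
# across the six direct metrics (NA agreement counts as a match)
metric_oracle_gap <- function(A) {
  cmp <- function(a, b) {
    if (is.na(a) && is.na(b)) return(0)
    if (is.na(a) || is.na(b)) return(Inf)
    abs(a - b)
  }
  # synchronizability is defined (errors otherwise) only for graphs with
  # positive total weight
  sync_gap <- if (sum(A) > 0)
    cmp(synchronizability(A), oracle_synchronizability(A)) else 0
  # clustering needs at least 3 nodes for a triangle to exist
  clus_gap <- if (nrow(A) >= 3)
    cmp(clustering_coefficient(A), oracle_clustering(A)) else 0
  suppressWarnings(max(
    cmp(network_density(A), oracle_density(A)),
    clus_gap,
    cmp(as.numeric(characteristic_path_length(A)), oracle_cpl(A)),
    cmp(assortativity_coef(A), oracle_assortativity(A)),
    cmp(spectral_radius(A), oracle_spectral_radius(A)),
    sync_gap
  ))
}

# small toy settings reused across tests: short segments keep runtimes low
toy_spec <- function(...) {
  cohort_spec(n_focal = 1, n_bilateral = 1, n_interictal = 1,
              n_channels = 8, fs = 500, segment_length = 120,
              onset_offset = 60, seed = 42, ...)
}
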