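# Weighted graph statistics: analytic values, brute-force oracle
# agreement, and the scale / relabeling invariances.

K <- function(n, w = 1) { A <- matrix(w, n, n); diag(A) <- 0; A }
path_graph <- function(n, w = 1) {
  A <- matrix(0, n, n)
  for (i in seq_len(n - 1)) A[i, i + 1] <- A[i + 1, i] <- w
  A
}

test_that("density matches closed forms", {
  expect_equal(network_density(K(5)), 1)
  expect_equal(network_density(matrix(0, 5, 5)), 0)
  A <- matrix(0, 4, 4); A[1, 2] <- A[2, 1] <- 0.6
  expect_equal(network_density(A), 0.1)
})

test_that("clustering coefficient matches triangle formulas", {
  expect_equal(clustering_coefficient(K(3)), 1)
  expect_equal(clustering_coefficient(K(3, 0.125)), 0.125)
  star <- matrix(0, 4, 4); star[1, 2:4] <- star[2:4, 1] <- 1
  expect_equal(clustering_coefficient(star), 0)
})

test_that("characteristic path length uses inverse-weight distances", {
  expect_equal(as.numeric(characteristic_path_length(K(3))), 1)
  expect_equal(as.numeric(characteristic_path_length(K(3, 0.5))), 2)
  expect_equal(as.numeric(characteristic_path_length(path_graph(4))), 10 / 6)
  # disconnected pairs excluded and counted
  A <- matrix(0, 4, 4)
  A[1, 2] <- A[2, 1] <- 1; A[3, 4] <- A[4, 3] <- 1
  cpl <- characteristic_path_length(A)
  expect_equal(as.numeric(cpl), 1)
  expect_equal(attr(cpl, "n_excluded"), 4)
  expect_warning(res <- characteristic_path_length(matrix(0, 3, 3)))
  expect_true(is.na(res))
})

test_that("assortativity equals endpoint-strength correlation over oriented edges", {
  expect_equal(assortativity_coef(path_graph(4)), -0.5)
  two_edges <- matrix(0, 4, 4)
  two_edges[1, 2] <- two_edges[2, 1] <- 1
  two_edges[3, 4] <- two_edges[4, 3] <- 1
  expect_warning(r <- assortativity_coef(two_edges), "degenerate")
  expect_true(is.na(r))
  # two unit triangles joined by one edge vs brute force over 14 pairs
  A <- matrix(0, 6, 6); A[1:3, 1:3] <- K(3); A[4:6, 4:6] <- K(3)
  A[3, 4] <- A[4, 3] <- 1
  expect_equal(assortativity_coef(A), oracle_assortativity(A), tolerance = 1e-12)
})

test_that("spectral radius and synchronizability match eigen closed forms", {
  expect_equal(spectral_radius(K(3)), 2)
  w <- 0.37; A2 <- matrix(c(0, w, w, 0), 2)
  expect_equal(spectral_radius(A2), w)
  for (n in 3:6) expect_equal(synchronizability(K(n)), 1, tolerance = 1e-12)
  expect_equal(synchronizability(path_graph(3)), 1 / 3)
  disc <- matrix(0, 4, 4)
  disc[1, 2] <- disc[2, 1] <- 1; disc[3, 4] <- disc[4, 3] <- 1
  expect_equal(synchronizability(disc), 0)
})

test_that("modularity returns equation-consistent Q with expected partitions", {
  # single clique: one community is optimal, Q = 0
  res <- network_modularity(K(5))
  expect_equal(res$Q, 0)
  expect_equal(length(unique(res$membership)), 1)
  # two disconnected cliques: Q = 2 * (1/2 - 1/4) = 0.5
  A <- matrix(0, 6, 6); A[1:3, 1:3] <- K(3); A[4:6, 4:6] <- K(3)
  res <- network_modularity(A)
  expect_equal(res$Q, 0.5)
  expect_equal(length(unique(res$membership)), 2)
  expect_error(network_modularity(matrix(0, 3, 3)), "zero-weight")
  # returned Q always matches the printed equation on the returned
  # partition and is never below the one-community Q = 0
  set.seed(11)
  for (i in 1:30) {
    A <- random_graph(sample(4:7, 1), c(0, 0.3, 1))
    if (sum(A) == 0) next
    res <- network_modularity(A)
    expect_equal(res$Q, oracle_modularity_Q(A, res$membership),
                 tolerance = 1e-10)
    expect_gte(res$Q, 0)
  }
})

test_that("metrics agree with brute-force oracles on random small graphs", {
  set.seed(202)
  worst <- 0
  for (i in 1:200) {
    A <- random_graph(sample(3:6, 1), c(0, 0.3, 1))
    worst <- max(worst, metric_oracle_gap(A))
  }
  expect_lt(worst, 1e-8)
})

test_that("scaling weights by c scales metrics as expected", {
  set.seed(7)
  A <- random_graph(6, c(0, 0.3, 1))
  cc <- 2.7
  expect_equal(network_density(cc * A), cc * network_density(A))
  expect_equal(spectral_radius(cc * A), cc * spectral_radius(A))
  expect_equal(clustering_coefficient(cc * A), cc * clustering_coefficient(A))
  expect_equal(synchronizability(cc * A), synchronizability(A))
  expect_equal(assortativity_coef(cc * A), assortativity_coef(A))
  expect_equal(as.numeric(characteristic_path_length(cc * A)),
               as.numeric(characteristic_path_length(A)) / cc)
})

test_that("metrics are invariant under node relabeling", {
  set.seed(8)
  A <- random_graph(6, c(0, 0.3, 1))
  p <- sample(6)
  B <- A[p, p]
  expect_equal(graph_metrics(B)[metric_names != "modularity"],
               graph_metrics(A)[metric_names != "modularity"],
               tolerance = 1e-10)
  # modularity Q is label-invariant up to partition ties; both must be
  # equation-consistent and equal here (no ties in this draw)
  expect_equal(network_modularity(B)$Q, network_modularity(A)$Q,
               tolerance = 1e-10)
})

test_that("metric_timeseries evaluates all seven metrics per window and propagates NA", {
  N <- 6; W <- 5
  arr <- array(0, c(N, N, W))
  set.seed(3)
  base <- random_graph(N, c(0, 0.3, 1))
  for (w in 1:W) arr[, , w] <- base
  arr[, , 3] <- 0                       # one empty matrix mid-series
  series <- ictalnet:::new_connectivity_series(
    arr, window_starts = seq(0, by = 15, length.out = W), step = 15,
    stage = "rectified", fs = 500, condition = "focal", onset_time = 30)
  suppressWarnings(mt <- metric_timeseries(series))
  expect_equal(nrow(mt), W)
  expect_true(all(metric_names %in% names(mt)))
  expect_equal(mt$density[3], 0)
  expect_true(is.na(mt$path_length[3]))
  expect_true(is.na(mt$assortativity[3]))
  expect_true(is.na(mt$modularity[3]))
  # constant elsewhere: constant metric values
  expect_equal(mt$clustering[1], mt$clustering[5])
  expect_equal(mt$time_min, (mt$window_start - 30) / 60)
})
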