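# Bootstrap, permutation nulls, p-values, effect sizes, windowed
# averages and the repeated-measures ANOVA.

const_panel <- function(v, n, T_, cond = "a") {
  metric_panel(matrix(v, n, T_), cond, times = seq_len(T_))
}

test_that("bootstrap of constant panels is exact", {
  pA <- const_panel(3, 1, 4, "focal")
  boot <- bootstrap_difference(pA, pA, B = 50, seed = 1)
  expect_true(all(boot$diff == 0))
  expect_equal(boot$ci_lower, rep(0, 4))
  expect_equal(boot$ci_upper, rep(0, 4))
  pB <- const_panel(1.25, 6, 4, "bilateral")
  pA6 <- const_panel(3, 6, 4, "focal")
  boot2 <- bootstrap_difference(pA6, pB, B = 50, seed = 1)
  expect_true(all(boot2$diff == 3 - 1.25))
  expect_error(bootstrap_difference(metric_panel(matrix(0, 0, 4), "x"), pB),
               "empty")
})

test_that("bootstrap CI covers zero under the null at nominal-ish rate", {
  set.seed(31)
  hits <- 0; total <- 0
  for (rep in 1:200) {
    pA <- metric_panel(matrix(rnorm(20 * 10), 20), "a", 1:10)
    pB <- metric_panel(matrix(rnorm(20 * 10), 20), "b", 1:10)
    boot <- bootstrap_difference(pA, pB, B = 200, seed = rep)
    hits <- hits + sum(boot$ci_lower <= 0 & boot$ci_upper >= 0)
    total <- total + 10
  }
  expect_gte(hits / total, 0.90)
})

test_that("permutation null preserves group sizes and centres at zero", {
  set.seed(32)
  pA <- metric_panel(matrix(rnorm(49 * 5), 49), "focal", 1:5)
  pB <- metric_panel(matrix(rnorm(18 * 5, 1), 18), "bilateral", 1:5)
  null <- permutation_null(pA, pB, B = 2000, seed = 2)
  expect_equal(unname(null$sizes), c(49, 18))
  # each null mean within 3 Monte-Carlo SEs of 0
  se <- apply(null$null, 2, stats::sd) / sqrt(nrow(null$null))
  expect_true(all(abs(colMeans(null$null)) <= 3 * se))
  # B = 1 single reproducible shuffle
  n1 <- permutation_null(pA, pB, B = 1, seed = 9)
  n2 <- permutation_null(pA, pB, B = 1, seed = 9)
  expect_identical(n1$null, n2$null)
  expect_equal(dim(n1$null), c(1L, 5L))
})

test_that("identical panels give a null equal in law to the bootstrap difference", {
  set.seed(33)
  X <- matrix(rnorm(30 * 3), 30)
  pA <- metric_panel(X, "a", 1:3); pB <- metric_panel(X, "b", 1:3)
  boot <- bootstrap_difference(pA, pB, B = 3000, seed = 5)
  null <- permutation_null(pA, pB, B = 3000, seed = 6)
  for (t in 1:3) {
    se <- stats::sd(boot$diff[, t]) / sqrt(3000)
    expect_lt(abs(mean(boot$diff[, t])), 3 * se + 1e-6)
    # matched spread between the two resampling laws (within 25%)
    expect_lt(abs(stats::sd(boot$diff[, t]) / stats::sd(null$null[, t]) - 1),
              0.25)
  }
})

test_that("p-values double the smaller tail and floor at 1/B", {
  times <- 1:2
  # difference distribution entirely above 0 at t1; symmetric at t2
  diff <- cbind(abs(rnorm(10000)) + 0.1, c(rnorm(10000)))
  boot <- list(diff = diff, mean = colMeans(diff), times = times)
  ps <- p_value(boot)
  expect_equal(ps$p_boot[1], 1e-4)
  expect_gt(ps$p_boot[2], 0.5)
  # half the mass exactly below zero -> doubling caps at 1
  diff2 <- cbind(rep(c(-1, 1), 500))
  boot2 <- list(diff = diff2, mean = 0, times = 1)
  expect_equal(p_value(boot2)$p_boot, 1)
  # null-based estimate is primary when a null is supplied
  null <- list(null = matrix(rnorm(10000 * 2, sd = 0.01), 10000), times = times)
  ps2 <- p_value(boot, null)
  expect_equal(ps2$p, ps2$p_null)
  expect_equal(ps2$p_null[1], 1e-4)      # observed mean far in the tail
  expect_equal(min(ps2$p), 1 / 10000)
})

test_that("Cohen's d on bootstrapped means is 0 for identical panels and grows with n", {
  pA <- const_panel(2, 5, 3)
  boot <- bootstrap_difference(pA, pA, B = 100, seed = 3)
  d <- cohens_d(boot)
  expect_true(all(!is.finite(d$d) | d$d == 0))
  # N(1,1) vs N(0,1): |d| on mean distributions is much larger than the
  # per-observation d (~1) and grows ~ sqrt(n)
  set.seed(34)
  d_at_n <- vapply(c(50, 200), function(n) {
    pX <- metric_panel(matrix(rnorm(n, 1), n, 1), "x", 1)
    pY <- metric_panel(matrix(rnorm(n, 0), n, 1), "y", 1)
    b <- bootstrap_difference(pX, pY, B = 1000, seed = n)
    abs(cohens_d(b)$d)
  }, 0)
  expect_gt(d_at_n[1], 3)
  expect_gt(d_at_n[2], d_at_n[1])
  # effect-size route (i): mean of difference distribution ~ true mean gap
  pX <- metric_panel(matrix(rnorm(400, 1), 400, 1), "x", 1)
  pY <- metric_panel(matrix(rnorm(400, 0), 400, 1), "y", 1)
  b <- bootstrap_difference(pX, pY, B = 2000, seed = 1)
  expect_equal(mean(b$diff), mean(pX$values) - mean(pY$values),
               tolerance = 0.01)
})

test_that("d_min is reported within significant runs with a percentile CI", {
  set.seed(35)
  shift <- c(0, 0, 1.5, 2, 0)            # significant only at t3, t4
  X <- matrix(rnorm(40 * 5), 40)
  Y <- sweep(matrix(rnorm(40 * 5), 40), 2, shift, "+")
  pA <- metric_panel(Y, "a", 1:5); pB <- metric_panel(X, "b", 1:5)
  gc <- compare_groups(pA, pB, B = 1000, seed = 4)
  expect_false(is.null(gc$d_min))
  expect_true(gc$d_min$time %in% gc$times[gc$p < 0.05])
  expect_lte(gc$d_min$ci[1], gc$d_min$ci[2])
  sig_d <- abs(gc$d[gc$p < 0.05])
  expect_equal(gc$d_min$value, min(sig_d))
  # no significant points -> no d_min
  gc0 <- compare_groups(metric_panel(X, "a", 1:5),
                        metric_panel(X + 0, "b", 1:5), B = 500, seed = 5)
  expect_null(gc0$d_min)
})

test_that("significant intervals map runs to [start, last start + stride]", {
  times <- seq(-15, 9.75, by = 0.25)
  n <- length(times)
  p <- rep(1, n)
  expect_equal(nrow(significant_intervals(p, times)), 0)
  # windows starting 2.25..9.75 min post-onset significant
  sel <- times >= 2.25 & times <= 9.75
  p[sel] <- 0.01
  iv <- significant_intervals(p, times)
  expect_equal(iv$start_min, 2.25)
  expect_equal(iv$end_min, 10)
  # two separated runs: sorted, non-overlapping
  p <- rep(1, n); p[5:8] <- 0.01; p[60:61] <- 0.03
  iv2 <- significant_intervals(p, times)
  expect_equal(nrow(iv2), 2)
  expect_lt(iv2$end_min[1], iv2$start_min[2])
})

test_that("window averages tile the segment into five 5-min spans", {
  times <- seq(-15, by = 0.25, length.out = 98)
  wa <- window_averages(rep(2.5, 98), times)
  expect_equal(unname(wa), rep(2.5, 5))
  expect_equal(names(wa), c("preictal1", "preictal2", "preictal3",
                            "ictal", "postictal"))
  # strictly increasing series -> strictly increasing window means
  wa2 <- window_averages(seq_len(98), times)
  expect_true(all(diff(wa2) > 0))
  # a window starting exactly at 0 min belongs to the ictal bin
  v <- as.numeric(times == 0)
  wa3 <- window_averages(v, times)
  expect_equal(unname(wa3["preictal3"]), 0)
  expect_gt(wa3["ictal"], 0)
})

test_that("rm_anova decomposes condition, window and interaction effects", {
  wcols <- c("preictal1", "preictal2", "preictal3", "ictal", "postictal")
  mk <- function(M, cond) {
    d <- as.data.frame(M); names(d) <- wcols
    cbind(data.frame(segment_id = paste0(cond, seq_len(nrow(M))),
                     condition = cond), d)
  }
  # all values identical -> F = 0 for all effects
  flat <- rbind(mk(matrix(1, 10, 5), "a"), mk(matrix(1, 10, 5), "b"))
  res <- rm_anova(flat)
  expect_equal(res$anova$F, rep(0, 3))
  # condition shifted by a constant: condition effect, no interaction
  set.seed(36)
  base <- matrix(rnorm(20 * 5, sd = 1), 20)
  shifted <- matrix(rnorm(20 * 5, mean = 5, sd = 1), 20)
  res2 <- rm_anova(rbind(mk(base, "a"), mk(shifted, "b")))
  a2 <- res2$anova
  expect_lt(a2$p[a2$effect == "condition"], 0.001)
  expect_gt(a2$p[a2$effect == "condition:window"], 0.05)
  # within-unit window effect injected equally in all conditions
  wshift <- matrix(rep(c(0, 0, 0, 5, 5), each = 20), 20)
  res3 <- rm_anova(rbind(mk(base + wshift, "a"),
                         mk(matrix(rnorm(20 * 5), 20) + wshift, "b")))
  a3 <- res3$anova
  expect_lt(a3$p[a3$effect == "window"], 0.001)
  expect_gt(a3$p[a3$effect == "condition"], 0.05)
  # post hoc paired t-tests cover window pairs within condition
  expect_true(all(c("condition", "window_a", "window_b", "t", "p") %in%
                    names(res3$posthoc)))
  expect_equal(nrow(res3$posthoc), 2 * choose(5, 2))
  ph <- res3$posthoc
  expect_lt(ph$p[ph$condition == "a" & ph$window_a == "preictal1" &
                   ph$window_b == "ictal"], 0.001)
  # a condition with < 2 units is rejected
  expect_error(rm_anova(rbind(mk(base, "a"), mk(matrix(1, 1, 5), "b"))),
               "at least 2")
})

test_that("fixed seeds reproduce comparisons bit-for-bit", {
  set.seed(37)
  pA <- metric_panel(matrix(rnorm(12 * 6), 12), "a", 1:6)
  pB <- metric_panel(matrix(rnorm(9 * 6), 9), "b", 1:6)
  g1 <- compare_groups(pA, pB, B = 300, seed = 11)
  g2 <- compare_groups(pA, pB, B = 300, seed = 11)
  expect_identical(g1[c("mean", "ci_lower", "ci_upper", "p", "d")],
                   g2[c("mean", "ci_lower", "ci_upper", "p", "d")])
})
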