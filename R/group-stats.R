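# Time-resolved group comparison: seizure-level bootstrap, shuffled-label
# permutation nulls, doubled one-tailed p-values, Cohen's d and d_min,
# significant-interval extraction, 5-min windowed averages and
# repeated-measures ANOVA.

#' Assemble a metric panel
#'
#' A panel is the segments x time-points matrix of one metric for one
#' condition — the unit on which all group statistics operate.
#'
#' @param values Numeric matrix, one row per segment, one column per
#'   smoothed window.
#' @param condition Condition label.
#' @param times Window times in minutes relative to onset (one per column).
#' @return A `metric_panel` object.
#' @export
metric_panel <- function(values, condition, times = NULL) {
  values <- as.matrix(values)
  if (is.null(times)) times <- seq_len(ncol(values))
  stopifnot(length(times) == ncol(values))
  structure(list(values = values, condition = condition, times = times),
            class = "metric_panel")
}

#' Collect one metric across segments into per-condition panels
#'
#' @param metric_tables List of data frames from [metric_timeseries()]
#'   (each carrying a `condition` attribute).
#' @param metric Metric name (one of the seven).
#' @return Named list of `metric_panel`s, one per condition present.
#' @export
panels_from_metrics <- function(metric_tables, metric) {
  conds <- vapply(metric_tables, function(m) attr(m, "condition"), "")
  out <- list()
  for (cond in unique(conds)) {
    rows <- metric_tables[conds == cond]
    vals <- do.call(rbind, lapply(rows, function(m) m[[metric]]))
    out[[cond]] <- metric_panel(vals, cond, times = rows[[1]]$time_min)
  }
  out
}

#' Bootstrap distribution of per-time-point mean differences
#'
#' Resamples whole segments (rows) with replacement `B` times,
#' independently within each panel, takes per-time-point means and records
#' `mean(A*) - mean(B*)` for each iteration.
#'
#' @param panelA,panelB `metric_panel`s sharing the time axis.
#' @param B Number of bootstrap iterations (default 10000).
#' @param seed Integer seed.
#' @return List with `diff` (B x T matrix), `bootA`/`bootB` (B x T
#'   per-condition bootstrap means), `mean`, `ci_lower`, `ci_upper`
#'   (percentile 95% CI) and `times`.
#' @export
bootstrap_difference <- function(panelA, panelB, B = 10000, seed = 1L) {
  stopifnot(inherits(panelA, "metric_panel"), inherits(panelB, "metric_panel"),
            B >= 1)
  if (nrow(panelA$values) == 0 || nrow(panelB$values) == 0)
    stop("empty panel")
  if (!isTRUE(all.equal(panelA$times, panelB$times)))
    stop("panels must share the time axis")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  bootA <- .boot_means(panelA$values, B)
  bootB <- .boot_means(panelB$values, B)
  diff <- bootA - bootB
  list(diff = diff, bootA = bootA, bootB = bootB,
       mean = colMeans(diff),
       ci_lower = apply(diff, 2, stats::quantile, 0.025, names = FALSE),
       ci_upper = apply(diff, 2, stats::quantile, 0.975, names = FALSE),
       times = panelA$times, B = B)
}

# B x T matrix of bootstrap means of the rows of M (NAs excluded per
# column so undefined-metric markers do not poison whole iterations).
.boot_means <- function(M, B) {
  n <- nrow(M)
  idx <- matrix(sample.int(n, n * B, replace = TRUE), B, n)
  out <- matrix(0, B, ncol(M))
  for (t in seq_len(ncol(M))) {
    v <- M[, t]
    mt <- matrix(v[idx], B, n)
    out[, t] <- rowMeans(mt, na.rm = TRUE)
  }
  out
}

#' Shuffled-label permutation null of per-time-point mean differences
#'
#' Pools the rows of both panels, permutes the condition labels `B` times
#' preserving the group sizes, and records the per-time-point difference
#' of group means for each shuffle; each null distribution is centred
#' near zero.
#'
#' @inheritParams bootstrap_difference
#' @return List with `null` (B x T matrix) and `times`.
#' @export
permutation_null <- function(panelA, panelB, B = 10000, seed = 1L) {
  stopifnot(inherits(panelA, "metric_panel"), inherits(panelB, "metric_panel"),
            B >= 1)
  nA <- nrow(panelA$values); nB <- nrow(panelB$values)
  if (nA == 0 || nB == 0) stop("empty panel")
  if (!isTRUE(all.equal(panelA$times, panelB$times)))
    stop("panels must share the time axis")
  pool <- rbind(panelA$values, panelB$values)
  n <- nA + nB
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  perm <- matrix(0L, B, n)
  for (b in seq_len(B)) perm[b, ] <- sample.int(n)
  null <- matrix(0, B, ncol(pool))
  for (t in seq_len(ncol(pool))) {
    v <- pool[, t]
    vm <- matrix(v[perm], B, n)
    null[, t] <- rowMeans(vm[, seq_len(nA), drop = FALSE], na.rm = TRUE) -
      rowMeans(vm[, nA + seq_len(nB), drop = FALSE], na.rm = TRUE)
  }
  list(null = null, times = panelA$times, B = B,
       sizes = c(nA = nA, nB = nB))
}

#' Doubled one-tailed p-values per time point
#'
#' Two one-tailed tests against zero are combined by doubling the smaller
#' tail and capping at 1; the result is floored at `1/B` (the resolution
#' of a `B`-iteration resampling scheme, 0.0001 at B = 10000). Two
#' estimates are produced: `p_boot`, the wrong-side mass of the bootstrap
#' difference distribution, and `p_null`, the observed mean difference
#' located in the shuffled-label null; the null-based estimate is the
#' primary `p`.
#'
#' @param boot Result of [bootstrap_difference()].
#' @param null Result of [permutation_null()] (optional; when absent only
#'   `p_boot` is computed and used as `p`).
#' @return Data frame with columns `time`, `p`, `p_boot`, `p_null`.
#' @export
p_value <- function(boot, null = NULL) {
  B <- nrow(boot$diff)
  p_lo <- colMeans(boot$diff >= 0)   # evidence against "A < B"
  p_hi <- colMeans(boot$diff <= 0)   # evidence against "A > B"
  p_boot <- pmax(1 / B, pmin(1, 2 * pmin(p_lo, p_hi)))
  p_null <- rep(NA_real_, length(p_boot))
  if (!is.null(null)) {
    Bn <- nrow(null$null)
    obs <- boot$mean
    ge <- colMeans(sweep(null$null, 2, obs, ">="))
    le <- colMeans(sweep(null$null, 2, obs, "<="))
    p_null <- pmax(1 / Bn, pmin(1, 2 * pmin(ge, le)))
  }
  data.frame(time = boot$times,
             p = if (is.null(null)) p_boot else p_null,
             p_boot = p_boot, p_null = p_null)
}

#' Cohen's d on bootstrapped mean distributions, with d_min
#'
#' `d_t = (mean_A - mean_B) / s_pooled` computed on the bootstrapped
#' per-condition mean distributions at each time point. Within each
#' maximal run of consecutive significant time points, `d_min` is the
#' smallest `|d_t|`; its 95% CI is the percentile interval of the
#' per-iteration `d` at that time point. Note that because the bootstrap
#' mean distributions have standard deviation ~ s/sqrt(n), this estimator
#' scales like `sqrt(n)` times the classical per-observation d.
#'
#' @param boot Result of [bootstrap_difference()].
#' @param p_series Optional data frame from [p_value()]; needed for the
#'   `d_min` summary.
#' @param alpha Significance level (default 0.05).
#' @return List with `d` (per-time-point Cohen's d), and when significant
#'   points exist, `d_min` entries: `value` (= smallest `|d|`), `time`,
#'   `ci` (2.5/97.5 percentiles of per-iteration d at that point).
#' @export
cohens_d <- function(boot, p_series = NULL, alpha = 0.05) {
  sA <- apply(boot$bootA, 2, stats::sd)
  sB <- apply(boot$bootB, 2, stats::sd)
  s_pooled <- sqrt((sA^2 + sB^2) / 2)
  d <- (colMeans(boot$bootA) - colMeans(boot$bootB)) / s_pooled
  res <- list(d = d, times = boot$times)
  if (!is.null(p_series)) {
    sig <- p_series$p < alpha
    if (any(sig, na.rm = TRUE)) {
      runs <- .sig_runs(sig)
      dmins <- lapply(runs, function(r) {
        i_min <- r[which.min(abs(d[r]))]
        d_iter <- boot$diff[, i_min] / s_pooled[i_min]
        list(value = abs(d[i_min]), time = boot$times[i_min],
             ci = unname(stats::quantile(d_iter, c(0.025, 0.975))))
      })
      # report the overall smallest |d| across significant runs
      k <- which.min(vapply(dmins, `[[`, 0, "value"))
      res$d_min <- dmins[[k]]
      res$d_min_by_run <- dmins
    }
  }
  res
}

# maximal runs of TRUE; returns list of index vectors
.sig_runs <- function(sig) {
  sig[is.na(sig)] <- FALSE
  r <- rle(sig)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  Map(function(s, e) s:e, starts[r$values], ends[r$values])
}

#' Significant intervals from a p-value series
#'
#' Converts maximal runs of `p < alpha` to intervals
#' `[first window start, last window start + stride]` in minutes relative
#' to onset (stride 0.25 min under the default smoothing geometry).
#'
#' @param p Numeric vector of p-values.
#' @param times Window start times in minutes relative to onset.
#' @param alpha Significance level (default 0.05).
#' @param stride_min Window stride in minutes (default 0.25).
#' @return Data frame with columns `start_min`, `end_min` (possibly
#'   zero rows), sorted and non-overlapping.
#' @export
significant_intervals <- function(p, times, alpha = 0.05, stride_min = 0.25) {
  stopifnot(length(p) == length(times))
  runs <- .sig_runs(p < alpha)
  if (!length(runs))
    return(data.frame(start_min = numeric(), end_min = numeric()))
  out <- data.frame(
    start_min = vapply(runs, function(r) times[r[1L]], 0),
    end_min = vapply(runs, function(r) times[r[length(r)]] + stride_min, 0))
  out[order(out$start_min), , drop = FALSE]
}

#' Five-minute windowed averages of a metric series
#'
#' Means of the smoothed-window values whose start times fall in the five
#' consecutive 5-min spans tiling the 25-min segment: Preictal I
#' `[-15,-10)`, Preictal II `[-10,-5)`, Preictal III `[-5,0)`, ictal
#' `[0,5)` and postictal `[5,10)` minutes relative to onset (half-open, so
#' a window starting exactly at 0 is ictal).
#'
#' @param values Metric values, one per smoothed window.
#' @param times Window start times in minutes relative to onset.
#' @return Named numeric vector of the five window means.
#' @export
window_averages <- function(values, times) {
  stopifnot(length(values) == length(times))
  edges <- c(-15, -10, -5, 0, 5, 10)
  labels <- c("preictal1", "preictal2", "preictal3", "ictal", "postictal")
  out <- vapply(seq_len(5), function(k) {
    sel <- times >= edges[k] & times < edges[k + 1]
    mean(values[sel], na.rm = TRUE)
  }, 0)
  names(out) <- labels
  out
}

#' Two-way repeated-measures ANOVA on windowed summaries
#'
#' Time window (five levels) is the repeated within-unit factor and
#' seizure type the between-unit grouping factor; F statistics use
#' type-III sums of squares via the multivariate-linear-model
#' repeated-measures machinery, and sphericity-assumed univariate F tests
#' are reported. Post hoc two-tailed paired t-tests compare window pairs
#' within each condition.
#'
#' @param summaries Data frame with columns `segment_id`, `condition` and
#'   the five window-mean columns `preictal1`, `preictal2`, `preictal3`,
#'   `ictal`, `postictal` (one row per segment), e.g. built from
#'   [window_averages()].
#' @param posthoc_pairs Optional character matrix (2 columns) of window
#'   pairs for the follow-up t-tests; defaults to all 10 pairs.
#' @return List with `anova` (data frame: effect, F, p) and `posthoc`
#'   (data frame: condition, window pair, t, p).
#' @export
rm_anova <- function(summaries, posthoc_pairs = NULL) {
  wcols <- c("preictal1", "preictal2", "preictal3", "ictal", "postictal")
  stopifnot(all(c("condition", wcols) %in% names(summaries)))
  if (any(table(summaries$condition) < 2))
    stop("each condition needs at least 2 units")
  Y <- as.matrix(summaries[, wcols])
  cond <- factor(summaries$condition)
  df <- data.frame(cond = cond)
  mod <- stats::lm(Y ~ cond, data = df,
                   contrasts = list(cond = "contr.sum"))
  idata <- data.frame(window = factor(wcols, levels = wcols))
  aov_tab <- tryCatch({
    av <- car::Anova(mod, idata = idata, idesign = ~window, type = 3)
    # only the sphericity-assumed univariate tests are consumed, so the
    # sphericity-correction warnings for singular error SSP matrices
    # (degenerate inputs) are irrelevant here
    s <- suppressWarnings(summary(av, multivariate = FALSE))$univariate.tests
    keep <- rownames(s) != "(Intercept)"
    data.frame(effect = c("condition", "window", "condition:window"),
               ss = s[keep, "Sum Sq"],
               error_ss = s[keep, "Error SS"],
               F = s[keep, "F value"],
               p = s[keep, "Pr(>F)"],
               row.names = NULL)
  }, error = function(e) NULL)
  if (is.null(aov_tab))
    aov_tab <- data.frame(effect = c("condition", "window",
                                     "condition:window"),
                          ss = 0, error_ss = 0, F = NA_real_, p = NA_real_)
  # degenerate data (e.g. all values identical): zero effect SS and zero
  # error SS carry no evidence of any effect
  bad <- abs(aov_tab$ss) < 1e-10 &
    (abs(aov_tab$error_ss) < 1e-10 | !is.finite(aov_tab$F))
  aov_tab$F[bad] <- 0
  aov_tab$p[bad] <- 1
  if (is.null(posthoc_pairs))
    posthoc_pairs <- t(utils::combn(wcols, 2))
  ph <- do.call(rbind, lapply(levels(cond), function(cl) {
    sub <- Y[cond == cl, , drop = FALSE]
    do.call(rbind, lapply(seq_len(nrow(posthoc_pairs)), function(i) {
      a <- sub[, posthoc_pairs[i, 1]]; b <- sub[, posthoc_pairs[i, 2]]
      tt <- tryCatch(stats::t.test(a, b, paired = TRUE),
                     error = function(e) list(statistic = NA_real_,
                                              p.value = NA_real_))
      data.frame(condition = cl,
                 window_a = posthoc_pairs[i, 1],
                 window_b = posthoc_pairs[i, 2],
                 t = unname(tt$statistic), p = tt$p.value)
    }))
  }))
  list(anova = aov_tab, posthoc = ph)
}

#' Full time-resolved comparison of two conditions
#'
#' Runs the bootstrap, the permutation null, the doubled one-tailed
#' p-values, Cohen's d with d_min, and significant-interval extraction for
#' one metric and one pair of conditions. No multiple-testing correction
#' is applied across time points (per-time-point resampled p-values);
#' interpret runs of significance accordingly.
#'
#' @inheritParams bootstrap_difference
#' @param alpha Significance level (default 0.05).
#' @param stride_min Smoothed-window stride in minutes (default 0.25).
#' @return A `group_comparison` object: per-time-point `mean`,
#'   `ci_lower`, `ci_upper`, `p` (plus both p variants), `d`,
#'   `significant_intervals` and the `d_min` summary.
#' @export
compare_groups <- function(panelA, panelB, B = 10000, seed = 1L,
                           alpha = 0.05, stride_min = 0.25) {
  boot <- bootstrap_difference(panelA, panelB, B = B, seed = seed)
  null <- permutation_null(panelA, panelB, B = B, seed = seed + 1L)
  ps <- p_value(boot, null)
  d <- cohens_d(boot, ps, alpha = alpha)
  structure(list(
    conditions = c(panelA$condition, panelB$condition),
    times = boot$times,
    mean = boot$mean, ci_lower = boot$ci_lower, ci_upper = boot$ci_upper,
    p = ps$p, p_boot = ps$p_boot, p_null = ps$p_null,
    d = d$d, d_min = d$d_min,
    significant_intervals = significant_intervals(ps$p, boot$times,
                                                  alpha, stride_min),
    B = B, alpha = alpha, seed = seed),
    class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s vs %s | %d time points | B = %d\n",
              x$conditions[1], x$conditions[2], length(x$times), x$B))
  si <- x$significant_intervals
  if (nrow(si)) {
    cat("  significant (p <", x$alpha, ") intervals (min rel. onset):\n")
    for (i in seq_len(nrow(si)))
      cat(sprintf("    %.2f to %.2f\n", si$start_min[i], si$end_min[i]))
    if (!is.null(x$d_min))
      cat(sprintf("  Cohen's d_min = %.2f at %.2f min, 95%% CI (%.2f, %.2f)\n",
                  x$d_min$value, x$d_min$time, x$d_min$ci[1], x$d_min$ci[2]))
  } else cat("  no significant time points\n")
  invisible(x)
}
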