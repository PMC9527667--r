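# Sliding-window Pearson correlation networks with temporal smoothing and
# negative-weight rectification.

new_connectivity_series <- function(matrices, window_starts, step, stage,
                                    fs, segment_id = NA_character_,
                                    condition = NA_character_,
                                    onset_time = NA_real_,
                                    n_zero_var = 0L) {
  structure(list(matrices = matrices, window_starts = window_starts,
                 step = step, stage = stage, fs = fs,
                 segment_id = segment_id, condition = condition,
                 onset_time = onset_time, n_zero_var = n_zero_var),
            class = "connectivity_series")
}

#' @export
print.connectivity_series <- function(x, ...) {
  d <- dim(x$matrices)
  cat(sprintf("<connectivity_series> %s | %d x %d nodes x %d windows (step %g s)\n",
              x$stage, d[1], d[2], d[3], x$step))
  if (x$n_zero_var > 0)
    cat("  zero-variance channel-window events:", x$n_zero_var, "\n")
  invisible(x)
}

#' Sliding-window correlation networks
#'
#' Divides a segment into consecutive windows of `win` seconds advanced by
#' `step` seconds (defaults: 1-s windows overlapping by 0.5 s) and computes
#' the matrix of pairwise Pearson correlations of the windowed channel
#' signals in each, with the diagonal forced to zero. Only fully contained
#' windows are used: a 1500-s segment at the defaults yields
#' `(1500 - 1)/0.5 + 1 = 2999` matrices.
#'
#' A channel with zero variance inside a window has its correlations set
#' to 0 for that window; such events are counted in the `n_zero_var` field
#' of the result.
#'
#' @param seg An `ecog_segment` (preprocessed).
#' @param win Window length in seconds (default 1).
#' @param step Window step in seconds (default 0.5).
#' @return A `connectivity_series` at stage `"raw"` with entries in
#'   `[-1, 1]`.
#' @export
sliding_correlation <- function(seg, win = 1, step = 0.5) {
  stopifnot(inherits(seg, "ecog_recording"))
  fs <- seg$fs
  wn <- round(win * fs)
  sn <- round(step * fs)
  if (wn < 2) stop("window must contain at least 2 samples")
  X <- t(seg$samples)                       # time x channels
  T_len <- nrow(X)
  if (T_len < wn) stop("segment shorter than one window")
  n_win <- floor((T_len - wn) / sn) + 1L
  N <- ncol(X)
  out <- array(0, dim = c(N, N, n_win))
  n_zero <- 0L

  if (wn %% sn == 0) {
    # Exact block decomposition: each window is win/step consecutive
    # step-sized blocks, so per-block sums and cross-products give every
    # window's correlation matrix without touching samples twice.
    nb_per_win <- wn %/% sn
    n_blocks <- n_win + nb_per_win - 1L
    S <- matrix(0, n_blocks, N)
    CP <- array(0, dim = c(N, N, n_blocks))
    for (b in seq_len(n_blocks)) {
      idx <- ((b - 1L) * sn + 1L):((b - 1L) * sn + sn)
      Xb <- X[idx, , drop = FALSE]
      S[b, ] <- colSums(Xb)
      CP[, , b] <- crossprod(Xb)
    }
    for (w in seq_len(n_win)) {
      bs <- w:(w + nb_per_win - 1L)
      Sw <- colSums(S[bs, , drop = FALSE])
      CPw <- CP[, , bs[1L]]
      for (b in bs[-1L]) CPw <- CPw + CP[, , b]
      Cov <- (CPw - outer(Sw, Sw) / wn) / (wn - 1)
      v <- diag(Cov)
      zero <- v <= 0 | v <= 1e-10 * diag(CPw) / (wn - 1)
      n_zero <- n_zero + sum(zero)
      sdv <- sqrt(pmax(v, 0)); sdv[zero] <- 1
      R <- Cov / outer(sdv, sdv)
      R[zero, ] <- 0; R[, zero] <- 0
      R <- pmin(pmax(R, -1), 1)
      diag(R) <- 0
      out[, , w] <- (R + t(R)) / 2
    }
  } else {
    for (w in seq_len(n_win)) {
      idx <- ((w - 1L) * sn + 1L):((w - 1L) * sn + wn)
      Xw <- X[idx, , drop = FALSE]
      sds <- apply(Xw, 2, stats::sd)
      zero <- sds == 0
      n_zero <- n_zero + sum(zero)
      R <- suppressWarnings(stats::cor(Xw))
      R[zero, ] <- 0; R[, zero] <- 0
      diag(R) <- 0
      out[, , w] <- R
    }
  }
  new_connectivity_series(out,
                          window_starts = (seq_len(n_win) - 1L) * step,
                          step = step, stage = "raw", fs = fs,
                          segment_id = seg$segment_id %||% NA_character_,
                          condition = seg$condition %||% NA_character_,
                          onset_time = seg$onset_time %||% NA_real_,
                          n_zero_var = n_zero)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Temporal smoothing of a raw connectivity series
#'
#' Element-wise mean of each block of `span` seconds of consecutive raw
#' matrices, blocks advanced by `stride` seconds; only full blocks are
#' kept and each smoothed window is stamped with its block's first raw
#' window start. With the defaults (30-s span, 15-s stride) a 2999-matrix
#' raw series smooths to 98 matrices.
#'
#' @param series A `connectivity_series` at stage `"raw"`.
#' @param span Smoothing window in seconds (default 30); must be an
#'   integer multiple of the raw step.
#' @param stride Advance between smoothed windows in seconds (default 15);
#'   must be an integer multiple of the raw step.
#' @return A `connectivity_series` at stage `"smoothed"`.
#' @export
smooth_connectivity <- function(series, span = 30, stride = 15) {
  stopifnot(inherits(series, "connectivity_series"))
  if (series$stage != "raw")
    stop("smoothing applies to the raw series")
  step <- series$step
  if (abs(span / step - round(span / step)) > 1e-9 ||
      abs(stride / step - round(stride / step)) > 1e-9)
    stop("span and stride must be integer multiples of the raw step")
  block <- round(span / step)
  adv <- round(stride / step)
  n_raw <- dim(series$matrices)[3L]
  if (block > n_raw) stop("smoothing span exceeds series length")
  n_s <- floor((n_raw - block) / adv) + 1L
  N <- dim(series$matrices)[1L]
  out <- array(0, dim = c(N, N, n_s))
  for (w in seq_len(n_s)) {
    i0 <- (w - 1L) * adv + 1L
    out[, , w] <- rowMeans(series$matrices[, , i0:(i0 + block - 1L),
                                           drop = FALSE], dims = 2)
  }
  res <- series
  res$matrices <- out
  res$window_starts <- series$window_starts[((seq_len(n_s) - 1L) * adv) + 1L]
  res$step <- stride
  # a series rectified at the raw stage stays rectified after averaging
  res$stage <- if (isTRUE(attr(series, "rectified"))) "rectified" else "smoothed"
  res
}

#' Group channels into regions by averaging correlations
#'
#' Optional node redefinition: with a per-channel region map, each pair
#' of regions gets the mean correlation over its channel pairs (within a
#' region, the mean over distinct channel pairs), so nodes become regions
#' instead of individual contacts. The default pipeline uses the identity
#' map (node = channel).
#'
#' @param series A `connectivity_series` (any stage).
#' @param regions Character or factor vector, one region label per
#'   channel.
#' @return A `connectivity_series` over the unique regions (in first-
#'   appearance order), same stage and time stamps.
#' @export
group_regions <- function(series, regions) {
  stopifnot(inherits(series, "connectivity_series"))
  N <- dim(series$matrices)[1L]
  if (length(regions) != N)
    stop("need one region label per channel")
  regions <- as.character(regions)
  labs <- unique(regions)
  R <- length(labs)
  W <- dim(series$matrices)[3L]
  out <- array(0, dim = c(R, R, W))
  idx <- lapply(labs, function(l) which(regions == l))
  for (a in seq_len(R)) for (b in seq_len(a)) {
    ia <- idx[[a]]; ib <- idx[[b]]
    for (w in seq_len(W)) {
      block <- series$matrices[ia, ib, w, drop = FALSE][, , 1, drop = TRUE]
      block <- matrix(block, length(ia), length(ib))
      v <- if (a == b) {
        if (length(ia) < 2) 0 else mean(block[upper.tri(block)])
      } else mean(block)
      out[a, b, w] <- out[b, a, w] <- v
    }
  }
  for (w in seq_len(W)) diag(out[, , w]) <- 0
  res <- series
  res$matrices <- out
  res
}

#' Rectify a connectivity series
#'
#' Sets negative correlation values to zero, so entries lie in `[0, 1]`;
#' symmetry and the zero diagonal are preserved. By default applied to the
#' smoothed series (rectification after smoothing); pass a raw series to
#' rectify before smoothing instead.
#'
#' @param series A `connectivity_series` (stage `"smoothed"` or `"raw"`).
#' @return The series with negative entries clipped to 0 and stage set to
#'   `"rectified"` (from smoothed) or kept `"raw"` with attribute
#'   `rectified = TRUE` (from raw).
#' @export
rectify <- function(series) {
  stopifnot(inherits(series, "connectivity_series"))
  series$matrices[series$matrices < 0] <- 0
  if (series$stage == "smoothed") {
    series$stage <- "rectified"
  } else {
    attr(series, "rectified") <- TRUE
  }
  series
}
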