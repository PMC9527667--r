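# Filtering and prewhitening. Both operations are channel-local and
# zero-phase so that phase relationships (and hence correlations) between
# channels are preserved.

#' Band-pass and notch filter a recording
#'
#' Applies, per channel, a zero-phase 4th-order Butterworth band-pass and
#' a zero-phase biquad notch of quality factor `q` at the powerline
#' frequency. Zero-phase application (the squared magnitude response of
#' each designed filter, i.e. forward-backward filtering) preserves the
#' inter-channel phase relationships that the windowed correlations
#' depend on. Defaults reproduce the 1-70 Hz analysis band with a 60 Hz
#' notch.
#'
#' @param rec An `ecog_recording` (or `ecog_segment`).
#' @param low,high Band edges in Hz; must satisfy `0 < low < high < fs/2`.
#' @param notch Notch centre frequency in Hz, or `NULL`/`NA` to disable.
#'   Must lie inside the pass band when enabled.
#' @param q Notch quality factor (centre frequency / -3 dB bandwidth).
#' @return The recording with filtered samples; other fields unchanged.
#' @export
bandpass_notch <- function(rec, low = 1, high = 70, notch = 60, q = 30) {
  stopifnot(inherits(rec, "ecog_recording"))
  fs <- rec$fs
  if (!(low > 0 && low < high && high < fs / 2))
    stop("band edges must satisfy 0 < low < high < fs/2 = ", fs / 2)
  use_notch <- !is.null(notch) && !is.na(notch)
  if (use_notch && !(notch > low && notch < high))
    stop("notch frequency must lie inside the pass band")
  bp <- signal::butter(4, c(low, high) / (fs / 2), type = "pass")
  filters <- list(list(b = bp$b, a = bp$a))
  if (use_notch) {
    nf <- .notch_biquad(notch, fs, q)
    filters <- c(filters, list(list(b = nf$b, a = nf$a)))
  }
  rec$samples <- .zero_phase_filter(rec$samples, filters)
  rec
}

# RBJ-cookbook notch biquad at f0 Hz with quality factor q.
.notch_biquad <- function(f0, fs, q) {
  w0 <- 2 * pi * f0 / fs
  alpha <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  signal::Arma(b = b / a[1], a = a / a[1])
}

#' Prewhiten each channel with a first-order autoregressive model
#'
#' Per channel, the AR(1) coefficient `phi` is estimated as the lag-1
#' autocorrelation of the mean-removed signal over the full segment
#' (Yule-Walker at lag 1) and the channel is replaced by the innovation
#' `x_t - phi * x_{t-1}`. The first sample is dropped and the tail padded
#' by repeating the last value, so the segment length (and downstream
#' window count) is preserved and identical across channels. A
#' zero-variance channel gets `phi = 0` (left unchanged) with a warning.
#'
#' @param seg An `ecog_segment` (any `ecog_recording` works).
#' @return The segment with prewhitened samples and a numeric attribute
#'   `phi` giving each channel's estimated AR(1) coefficient.
#' @export
prewhiten_ar1 <- function(seg) {
  stopifnot(inherits(seg, "ecog_recording"))
  X <- seg$samples
  T_len <- ncol(X)
  if (T_len < 2) stop("segment must have at least 2 samples per channel")
  X <- X - rowMeans(X)
  denom <- rowSums(X^2)
  zero <- denom <= 0
  if (any(zero)) {
    warning("zero-variance channel(s) ", paste(which(zero), collapse = ", "),
            ": phi set to 0")
    denom[zero] <- 1
  }
  phis <- unname(rowSums(X[, -1L, drop = FALSE] * X[, -T_len, drop = FALSE]) /
                   denom)
  phis[zero] <- 0
  Y <- X[, -1L, drop = FALSE] - phis * X[, -T_len, drop = FALSE]
  seg$samples <- cbind(Y, Y[, T_len - 1L])  # drop first sample, repeat-pad
  attr(seg, "phi") <- phis
  seg
}
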