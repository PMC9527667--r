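# Minimal EDF+C writer/reader for synthetic recordings: 16-bit samples,
# 1-second data records, one annotation channel carrying the onset as an
# EDF+ time-stamped annotation. Covers exactly the subset of the format
# this package emits; not a general-purpose EDF library.

.edf_pad <- function(x, width) {
  x <- substr(as.character(x), 1, width)
  formatC(x, width = width, flag = "-")
}

.edf_num <- function(x, width) {
  s <- formatC(x, format = "g", digits = width - 2)
  if (nchar(s) > width) s <- substr(s, 1, width)
  formatC(s, width = width, flag = "-")
}

#' Write a segment to an EDF+ file
#'
#' 16-bit EDF+C with 1-s data records; channel labels encode hemisphere
#' (e.g. `L01`, `R03`) and the onset annotation (`seizure_onset` or
#' `pseudo_onset`) is stored in the annotation channel of the first data
#' record. Samples are scaled to the per-channel physical range, so the
#' round trip is exact to 16-bit quantization.
#'
#' @param seg An `ecog_segment` (or `ecog_recording`) whose duration is a
#'   whole number of seconds.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(seg, path) {
  stopifnot(inherits(seg, "ecog_recording"))
  X <- seg$samples
  fs <- seg$fs
  n_ch <- nrow(X)
  if (abs(fs - round(fs)) > 1e-9) stop("EDF writer requires an integer fs")
  fs <- as.integer(round(fs))
  n_rec <- ncol(X) / fs
  if (abs(n_rec - round(n_rec)) > 1e-9)
    stop("EDF writer requires a whole number of 1-s records")
  n_rec <- as.integer(round(n_rec))
  ann_samp <- 40L                      # 80 bytes of annotation per record
  ns <- n_ch + 1L

  # physical scaling: symmetric per-channel range, digital +/-32767
  pm <- apply(X, 1, function(x) max(abs(x), 1e-6))
  pm <- signif(pm * 1.0001, 6)
  dig <- round(sweep(X, 1, pm / 32767, "/"))

  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s) writeBin(charToRaw(s), con)
  wr(.edf_pad("0", 8))
  wr(.edf_pad("X X X X", 80))
  onset_lab <- if (nrow(seg$annotations))
    seg$annotations$label[1] else "onset"
  wr(.edf_pad("Startdate 01-JAN-2000 X X X", 80))
  wr(.edf_pad("01.01.00", 8))
  wr(.edf_pad("00.00.00", 8))
  wr(.edf_pad(as.character(256L * (ns + 1L)), 8))
  wr(.edf_pad("EDF+C", 44))
  wr(.edf_pad(as.character(n_rec), 8))
  wr(.edf_pad("1", 8))
  wr(.edf_pad(as.character(ns), 4))
  labels <- c(seg$channel_labels, "EDF Annotations")
  for (l in labels) wr(.edf_pad(l, 16))
  for (i in seq_len(ns)) wr(.edf_pad("", 80))              # transducer
  for (i in seq_len(ns)) wr(.edf_pad(if (i <= n_ch) "uV" else "", 8))
  for (i in seq_len(ns)) wr(.edf_num(if (i <= n_ch) -pm[i] else -1, 8))
  for (i in seq_len(ns)) wr(.edf_num(if (i <= n_ch) pm[i] else 1, 8))
  for (i in seq_len(ns)) wr(.edf_pad("-32768", 8))
  for (i in seq_len(ns)) wr(.edf_pad("32767", 8))
  for (i in seq_len(ns)) wr(.edf_pad("", 80))              # prefilter
  for (i in seq_len(ns)) wr(.edf_pad(as.character(if (i <= n_ch) fs else ann_samp), 8))
  for (i in seq_len(ns)) wr(.edf_pad("", 32))

  # annotation payloads: record-keeping TAL each record; onset TAL in rec 1
  onset_time <- if (!is.null(seg$onset_time)) seg$onset_time
                else if (nrow(seg$annotations)) seg$annotations$time[1] else NA
  ann_bytes <- lapply(seq_len(n_rec) - 1L, function(r) {
    tal <- c(charToRaw(sprintf("+%d", r)), as.raw(c(0x14, 0x14, 0x00)))
    if (r == 0L && is.finite(onset_time)) {
      tal <- c(tal, charToRaw(sprintf("+%g", onset_time)), as.raw(0x14),
               charToRaw(onset_lab), as.raw(c(0x14, 0x00)))
    }
    c(tal, raw(2L * ann_samp - length(tal)))
  })

  for (r in seq_len(n_rec)) {
    idx <- ((r - 1L) * fs + 1L):(r * fs)
    block <- as.integer(t(dig[, idx, drop = FALSE]))
    writeBin(block, con, size = 2L, endian = "little")
    writeBin(ann_bytes[[r]], con)
  }
  invisible(path)
}

#' Read an EDF/EDF+ file written by this package
#'
#' Parses the header, rescales the 16-bit samples to physical units,
#' decodes the hemisphere from the channel-label prefix and recovers the
#' onset annotation from the first data record's annotation channel.
#'
#' @param path EDF file path.
#' @return An `ecog_recording`.
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) rawToChar(readBin(con, "raw", n))
  rdt <- function(n) trimws(rd(n))
  rdt(8); rdt(80); rdt(80); rdt(8); rdt(8)
  rdt(8)                                  # header bytes
  rdt(44)
  n_rec <- as.integer(rdt(8))
  rec_dur <- as.numeric(rdt(8))
  ns <- as.integer(rdt(4))
  labels <- trimws(vapply(seq_len(ns), function(i) rd(16), ""))
  for (i in seq_len(ns)) rd(80)
  for (i in seq_len(ns)) rd(8)
  physmin <- as.numeric(vapply(seq_len(ns), function(i) rdt(8), ""))
  physmax <- as.numeric(vapply(seq_len(ns), function(i) rdt(8), ""))
  digmin <- as.numeric(vapply(seq_len(ns), function(i) rdt(8), ""))
  digmax <- as.numeric(vapply(seq_len(ns), function(i) rdt(8), ""))
  for (i in seq_len(ns)) rd(80)
  nsamp <- as.integer(vapply(seq_len(ns), function(i) rdt(8), ""))
  for (i in seq_len(ns)) rd(32)

  is_ann <- labels == "EDF Annotations"
  data_ch <- which(!is_ann)
  fs <- nsamp[data_ch[1]] / rec_dur
  X <- matrix(0, length(data_ch), n_rec * nsamp[data_ch[1]])
  ann_raw <- raw()
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      if (is_ann[i]) {
        b <- readBin(con, "raw", 2L * nsamp[i])
        if (r == 1L) ann_raw <- b
      } else {
        v <- readBin(con, "integer", nsamp[i], size = 2L, signed = TRUE,
                     endian = "little")
        j <- match(i, data_ch)
        scale <- (physmax[i] - physmin[i]) / (digmax[i] - digmin[i])
        X[j, ((r - 1L) * nsamp[i] + 1L):(r * nsamp[i])] <-
          physmin[i] + (v - digmin[i]) * scale
      }
    }
  }
  ann <- .parse_tals(ann_raw)
  hemi <- substr(labels[data_ch], 1, 1)
  if (!all(hemi %in% c("L", "R"))) hemi <- NULL
  ecog_recording(X, fs, channel_labels = labels[data_ch],
                 hemisphere = hemi, annotations = ann)
}

# decode time-stamped annotation lists from one annotation-channel block
.parse_tals <- function(b) {
  out <- data.frame(time = numeric(), label = character())
  if (!length(b)) return(out)
  bb <- b[b != as.raw(0)]
  if (!length(bb)) return(out)
  tals <- strsplit(rawToChar(bb), "\x14")[[1]]
  # pattern: "+t" then label tokens; keep tokens following a numeric stamp
  i <- 1
  while (i < length(tals)) {
    stamp <- suppressWarnings(as.numeric(tals[i]))
    lab <- tals[i + 1]
    if (is.finite(stamp) && nzchar(lab))
      out <- rbind(out, data.frame(time = stamp, label = lab))
    i <- i + 2
  }
  out
}

#' Write a ground-truth JSON sidecar
#'
#' Serializes the generator's ground truth (condition, community
#' assignment, gain knots, onset, sub-seed) next to a recording.
#'
#' @param gt Ground-truth list from [generate_segment()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(gt, path) {
  jsonlite::write_json(gt, path, auto_unbox = TRUE, digits = 10,
                       dataframe = "columns")
  invisible(path)
}

#' Write a segment's samples as a plain CSV matrix
#'
#' One column per channel (named by channel label), one row per sample.
#'
#' @param seg An `ecog_recording`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_segment_csv <- function(seg, path) {
  M <- t(seg$samples)
  colnames(M) <- seg$channel_labels
  utils::write.csv(M, path, row.names = FALSE)
  invisible(path)
}
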