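# Seeded synthetic multichannel ECoG with community-structured,
# time-varying coupling. A latent-factor model: each community shares a
# band-limited (4-30 Hz) Gaussian latent signal weighted by a
# time-varying within-community gain, a global latent signal weighted by
# the between-community gain couples communities, and independent channel
# noise is added after the shared part is normalized to unit variance, so
# coupling gains translate monotonically into expected correlations.

#' Cohort specification for the synthetic generator
#'
#' Defines the composition and geometry of a simulated cohort. The
#' defaults mirror the study conditions: 49 focal-remaining-focal,
#' 18 focal-to-bilateral and 67 interictal segments of 25 min (15 min
#' pre-onset, 10 min post-onset) at 500 Hz.
#'
#' @param n_focal,n_bilateral,n_interictal Segment counts per condition.
#' @param n_channels Channels per recording (>= 4).
#' @param hemisphere_split Fraction of channels tagged left (in (0,1)).
#' @param fs Sampling rate in Hz.
#' @param segment_length Segment duration in seconds (default 1500).
#' @param onset_offset Seconds from segment start to seizure onset (900).
#' @param seed Master integer seed; the same seed reproduces the cohort
#'   bit-identically.
#' @return A `cohort_spec` object.
#' @export
cohort_spec <- function(n_focal = 49, n_bilateral = 18, n_interictal = 67,
                        n_channels = 16, hemisphere_split = 0.5,
                        fs = 500, segment_length = 1500,
                        onset_offset = 900, seed = 1L) {
  stopifnot(n_focal >= 0, n_bilateral >= 0, n_interictal >= 0)
  if (n_channels < 4) stop("n_channels must be at least 4")
  if (!(hemisphere_split > 0 && hemisphere_split < 1))
    stop("hemisphere_split must lie in (0, 1)")
  if (!is.numeric(fs) || fs <= 0) stop("fs must be positive")
  if (onset_offset >= segment_length)
    stop("onset_offset must be smaller than segment_length")
  structure(list(n_focal = as.integer(n_focal),
                 n_bilateral = as.integer(n_bilateral),
                 n_interictal = as.integer(n_interictal),
                 n_channels = as.integer(n_channels),
                 hemisphere_split = hemisphere_split,
                 fs = fs, segment_length = segment_length,
                 onset_offset = onset_offset, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Coupling schedule for the synthetic generator
#'
#' Channels are partitioned into `n_communities` groups, each confined to
#' one hemisphere (half left, half right under the default split). Each
#' channel is built from its community's shared signal — a mixture of the
#' community latent (weight `within`) and a global latent (weight
#' `between`), normalized pointwise to unit variance — multiplied by a
#' synchrony amplitude, plus independent channel noise. The mixing gains
#' therefore shape the *pattern* of inter-channel correlation (community
#' structure versus global coupling), while the amplitude sets its
#' *level*; the two are controlled separately so that pre-onset and
#' post-onset effects cannot contaminate one another. All time courses
#' are piecewise linear with short ramps:
#' * baseline: mixing gains `within_base` / `between_base`, amplitude 1;
#' * post-onset, focal condition: the onset community's amplitude rises
#'   to `1 + post_sync_boost` (no contralateral change);
#' * post-onset, bilateral condition: the onset-hemisphere communities'
#'   amplitudes rise at onset, contralateral communities follow after
#'   `spread_delay` seconds, and the between-mixing gain is multiplied by
#'   `1 + post_between_boost` (global hypersynchrony);
#' * pre-onset, bilateral condition only: within-mixing is multiplied by
#'   `1 + preictal_magnitude` and between-mixing by
#'   `1 - preictal_magnitude` from segment start until onset — the
#'   injectable pre-onset signature (raised modularity, lowered spectral
#'   radius) at unchanged amplitude. `preictal_magnitude = 0` disables
#'   it;
#' * interictal: constant gains and amplitude throughout.
#'
#' @param n_communities Number of communities (>= 2, even under a 50/50
#'   hemisphere split so each hemisphere holds whole communities).
#' @param within_base,between_base Baseline mixing gains (>= 0).
#' @param noise_sigma Independent channel-noise amplitude relative to the
#'   unit-variance shared signal (baseline same-community correlation is
#'   `1 / (1 + noise_sigma^2)`).
#' @param post_sync_boost Post-onset relative amplitude increase of
#'   recruited communities (>= 0).
#' @param post_between_boost Post-onset relative increase of the
#'   between-mixing gain (bilateral condition, >= 0).
#' @param spread_delay Seconds after onset before contralateral
#'   communities recruit (bilateral condition).
#' @param preictal_magnitude Magnitude of the bilateral pre-onset
#'   signature in `[0, 1)`.
#' @param ramp Transition ramp length in seconds (piecewise-smooth gains).
#' @return A `coupling_schedule` object.
#' @export
coupling_schedule <- function(n_communities = 4, within_base = 1,
                              between_base = 0.6, noise_sigma = 1,
                              post_sync_boost = 1.5,
                              post_between_boost = 1,
                              spread_delay = 30,
                              preictal_magnitude = 0,
                              ramp = 2) {
  stopifnot(n_communities >= 2, within_base >= 0, between_base >= 0,
            noise_sigma >= 0, post_sync_boost >= 0,
            post_between_boost >= 0, spread_delay >= 0, ramp >= 0,
            preictal_magnitude >= 0, preictal_magnitude < 1)
  structure(list(n_communities = as.integer(n_communities),
                 within_base = within_base, between_base = between_base,
                 noise_sigma = noise_sigma,
                 post_sync_boost = post_sync_boost,
                 post_between_boost = post_between_boost,
                 spread_delay = spread_delay,
                 preictal_magnitude = preictal_magnitude,
                 ramp = ramp),
            class = "coupling_schedule")
}

# Deterministic sub-seed from (master seed, index); kept below 2^31.
derive_seed <- function(master, index) {
  as.integer((as.numeric(master) * 48271 + as.numeric(index) * 16807 + 12345) %%
               2147483629)
}

# Community assignment: communities are confined to one hemisphere; the
# first half of the communities live in the left hemisphere, the rest in
# the right. Returns list(membership, hemisphere).
.assign_communities <- function(n_channels, hemisphere_split, n_communities) {
  n_left <- max(1L, min(n_channels - 1L, round(n_channels * hemisphere_split)))
  hemi <- rep(c("L", "R"), c(n_left, n_channels - n_left))
  n_cl <- max(1L, floor(n_communities / 2))
  n_cr <- n_communities - n_cl
  mem <- integer(n_channels)
  mem[hemi == "L"] <- rep(seq_len(n_cl), length.out = n_left)
  mem[hemi == "R"] <- rep(n_cl + seq_len(n_cr), length.out = n_channels - n_left)
  list(membership = mem, hemisphere = hemi,
       community_hemi = rep(c("L", "R"), c(n_cl, n_cr)))
}

# Piecewise-linear gain time course evaluated on the sample grid.
# breaks: data.frame(t, gain) of knots; linear interpolation between,
# constant extrapolation outside.
.gain_course <- function(breaks, t_grid) {
  stats::approx(breaks$t, breaks$gain, xout = t_grid, rule = 2,
                ties = "ordered")$y
}

# Build per-community mixing-gain knots (within), global between-mixing
# knots and per-community amplitude knots for one condition. Times in
# seconds from segment start.
.schedule_knots <- function(spec, schedule, condition, community_hemi,
                            onset_community) {
  t_on <- spec$onset_offset
  t_end <- spec$segment_length
  r <- schedule$ramp
  wb <- schedule$within_base
  bb <- schedule$between_base
  mag <- schedule$preictal_magnitude
  n_com <- length(community_hemi)
  const <- function(v) data.frame(t = c(0, t_end), gain = c(v, v))

  within <- vector("list", n_com)
  amplitude <- vector("list", n_com)
  for (k in seq_len(n_com)) {
    within[[k]] <- if (condition == "bilateral" && mag > 0) {
      # pre-onset signature: community structure sharpened at unchanged
      # amplitude, relaxing to baseline at onset
      data.frame(t = c(0, t_on - r, t_on, t_end),
                 gain = c(wb * (1 + mag), wb * (1 + mag), wb, wb))
    } else const(wb)
    recruited <- switch(condition,
      interictal = FALSE,
      focal = k == onset_community,
      bilateral = TRUE)
    if (recruited) {
      t_boost <- if (condition == "bilateral" &&
                     community_hemi[k] != community_hemi[onset_community])
        t_on + schedule$spread_delay else t_on
      hi <- 1 + schedule$post_sync_boost
      amplitude[[k]] <- data.frame(t = c(0, t_boost, t_boost + r, t_end),
                                   gain = c(1, 1, hi, hi))
    } else {
      amplitude[[k]] <- const(1)
    }
  }
  between <- if (condition == "bilateral") {
    pre_b <- bb * (1 - mag)
    post_b <- bb * (1 + schedule$post_between_boost)
    data.frame(
      t = c(0, t_on - r, t_on, t_on + schedule$spread_delay,
            t_on + schedule$spread_delay + r, t_end),
      gain = c(pre_b, pre_b, bb, bb, post_b, post_b))
  } else const(bb)
  list(within = within, between = between, amplitude = amplitude)
}

# Band-limited (4-30 Hz) unit-variance Gaussian latent signals, one per
# row; drawn as white Gaussian noise and zero-phase band-passed inside the
# 1-70 Hz analysis band so preprocessing cannot remove the injected
# structure.
.latent_band <- function(n_sig, n, fs) {
  flt <- signal::butter(4, c(4, 30) / (fs / 2), type = "pass")
  W <- matrix(stats::rnorm(n_sig * n), n_sig, n)
  X <- .zero_phase_filter(W, list(list(b = flt$b, a = flt$a)))
  X / apply(X, 1, stats::sd)
}

#' Generate one synthetic segment
#'
#' Simulates one 25-min multichannel segment for a given condition. Each
#' channel is its community's shared signal — the unit-variance mixture
#' of the community latent and the global latent (both band-limited
#' 4-30 Hz), weighted by the time-varying mixing gains and scaled by the
#' synchrony amplitude — plus independent channel noise. Identical inputs
#' reproduce identical output.
#'
#' @param spec A [cohort_spec()].
#' @param schedule A [coupling_schedule()].
#' @param condition `"focal"`, `"bilateral"` or `"interictal"`.
#' @param seed Integer seed for this segment.
#' @param segment_id Optional identifier.
#' @return List with `segment` (an `ecog_segment`) and `ground_truth`
#'   (condition, community assignment, gain knots actually used, onset).
#' @export
generate_segment <- function(spec, schedule = coupling_schedule(),
                             condition = c("focal", "bilateral", "interictal"),
                             seed = spec$seed, segment_id = NA_character_) {
  stopifnot(inherits(spec, "cohort_spec"), inherits(schedule, "coupling_schedule"))
  condition <- match.arg(condition)
  asg <- .assign_communities(spec$n_channels, spec$hemisphere_split,
                             schedule$n_communities)
  n_com <- schedule$n_communities
  # onset community: first left-hemisphere community by convention
  onset_com <- which(asg$community_hemi == "L")[1L]
  knots <- .schedule_knots(spec, schedule, condition, asg$community_hemi,
                           onset_com)
  T_len <- round(spec$segment_length * spec$fs)
  t_grid <- (seq_len(T_len) - 1L) / spec$fs

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)

  lat_all <- .latent_band(n_com + 1L, T_len, spec$fs)
  latents <- t(lat_all[seq_len(n_com), , drop = FALSE])
  global <- lat_all[n_com + 1L, ]
  bg <- .gain_course(knots$between, t_grid)

  # the shared signal of a community is the gain-weighted latent mixture
  # normalized pointwise to unit variance (the latents are unit-variance,
  # so var = within^2 + between^2), scaled by the synchrony amplitude;
  # channels add independent noise on top
  shared <- vector("list", n_com)
  for (k in seq_len(n_com)) {
    wg <- .gain_course(knots$within[[k]], t_grid)
    amp <- .gain_course(knots$amplitude[[k]], t_grid)
    mix <- wg * latents[, k] + bg * global
    norm <- sqrt(wg^2 + bg^2)
    shared[[k]] <- amp * mix / ifelse(norm > 0, norm, 1)
  }
  X <- matrix(0, spec$n_channels, T_len)
  for (c_i in seq_len(spec$n_channels)) {
    X[c_i, ] <- shared[[asg$membership[c_i]]] +
      schedule$noise_sigma * stats::rnorm(T_len)
  }
  side <- asg$hemisphere
  labels <- sprintf("%s%02d", side, stats::ave(seq_along(side), side,
                                               FUN = seq_along))
  ann_label <- if (condition == "interictal") "pseudo_onset" else "seizure_onset"
  ann <- data.frame(time = spec$onset_offset,
                    label = c(ann_label, condition))
  seg <- as_segment(ecog_recording(X, spec$fs, labels, side, ann),
                    condition = condition, onset_time = spec$onset_offset,
                    segment_id = segment_id)
  gt <- list(condition = condition,
             communities = asg$membership,
             hemisphere = asg$hemisphere,
             onset_community = onset_com,
             within_gain_knots = knots$within,
             between_gain_knots = knots$between,
             amplitude_knots = knots$amplitude,
             onset_time = spec$onset_offset,
             seed = seed)
  list(segment = seg, ground_truth = gt)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Generate a full synthetic cohort
#'
#' Generates `n_focal + n_bilateral + n_interictal` segments, each with a
#' distinct sub-seed derived deterministically from the master seed and
#' segment index, so the cohort is a pure function of the spec.
#' Interictal segments have time-constant gain schedules.
#'
#' @param spec A [cohort_spec()].
#' @param schedule A [coupling_schedule()] shared by all segments.
#' @return List of `list(segment, ground_truth)` entries, focal first,
#'   then bilateral, then interictal.
#' @export
generate_cohort <- function(spec, schedule = coupling_schedule()) {
  stopifnot(inherits(spec, "cohort_spec"))
  conditions <- rep(c("focal", "bilateral", "interictal"),
                    c(spec$n_focal, spec$n_bilateral, spec$n_interictal))
  lapply(seq_along(conditions), function(i) {
    generate_segment(spec, schedule, conditions[i],
                     seed = derive_seed(spec$seed, i),
                     segment_id = sprintf("%s_%03d", conditions[i], i))
  })
}
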