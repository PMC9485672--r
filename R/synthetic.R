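#' Coupling specification for a simulated dyad
#'
#' Describes one simulated patient-therapist movement pair. Both members
#' move in intermittent bursts (motion energy is non-negative and mostly
#' quiet between gestures); coupling mixes a lagged copy of the leader's
#' burst envelope into the follower's envelope, so the coupling strength has
#' a clean monotone relation to measurable synchrony.
#'
#' @param alpha Coupling strength in `[0, 1]`: 0 = independent members,
#'   1 = the follower's envelope is an exact lagged copy of the leader's.
#' @param delta_s Coupling lag in seconds; the sign encodes who leads
#'   (positive = patient leads, negative = therapist leads), matching the
#'   lag convention of [windowed_lagged_crosscorr()].
#' @param burst_rate Movement bursts per minute (default 8, a gesture or
#'   posture shift every 7-8 s of conversation).
#' @param burst_dur_s Typical burst duration in seconds (default 2).
#' @param noise_sd SD of the additive sensor noise, in envelope amplitude
#'   units (burst amplitudes are lognormal with median 1); default 0.2.
#' @param duration_s Segment length in seconds (default 120).
#' @param fps Sampling rate in Hz (default 30).
#' @param seed Optional seed for reproducible generation.
#' @return A `coupling_spec` object.
#' @export
coupling_spec <- function(alpha = 0.5, delta_s = 0, burst_rate = 8,
                          burst_dur_s = 2, noise_sd = 0.2,
                          duration_s = 120, fps = 30, seed = NULL) {
  if (alpha < 0 || alpha > 1) stop("parameter error: alpha must be in [0, 1]")
  if (fps <= 0 || duration_s <= 0) stop("parameter error: fps and duration must be positive")
  if (abs(delta_s) >= duration_s)
    stop("parameter error: |delta_s| must be smaller than the duration")
  structure(list(alpha = alpha, delta_s = delta_s, burst_rate = burst_rate,
                 burst_dur_s = burst_dur_s, noise_sd = noise_sd,
                 duration_s = duration_s, fps = fps, seed = seed),
            class = "coupling_spec")
}

# sum of Poisson-timed boxcar bursts with lognormal amplitudes,
# lightly smoothed so burst edges are not perfectly sharp
burst_envelope <- function(n, fps, rate_per_min, dur_s) {
  env <- numeric(n)
  n_bursts <- rpois(1L, rate_per_min * n / (fps * 60))
  if (n_bursts > 0L) {
    onsets <- sample.int(n, n_bursts, replace = TRUE)
    amps <- rlnorm(n_bursts, meanlog = 0, sdlog = 0.5)
    durs <- pmax(1L, round(dur_s * fps * runif(n_bursts, 0.7, 1.3)))
    for (b in seq_len(n_bursts)) {
      span <- onsets[b]:min(n, onsets[b] + durs[b] - 1L)
      env[span] <- env[span] + amps[b]
    }
  }
  moving_average(env, max(1L, round(0.2 * fps)))
}

#' Generate one coupled dyadic movement segment
#'
#' The leader's signal is a non-negative burst process (Poisson-timed
#' bursts, boxcar amplitudes, additive truncated Gaussian noise) emulating
#' motion-energy morphology. The follower's envelope is
#' `alpha * lagged leader envelope + (1 - alpha) * independent burst
#' process`, plus its own noise. Who leads follows the sign of `delta_s`.
#'
#' @param spec A [coupling_spec()].
#' @param phase Segment label to attach.
#' @param dyad_id Dyad identifier to attach.
#' @return A [dyad_segment()] of `duration_s * fps` samples per member.
#' @export
gen_dyad <- function(spec, phase = "pretalk", dyad_id = "sim") {
  if (!inherits(spec, "coupling_spec")) stop("spec must be a coupling_spec")
  if (!is.null(spec$seed)) set.seed(spec$seed)
  n <- round(spec$duration_s * spec$fps)
  d <- abs(round(spec$delta_s * spec$fps))
  leader_env <- burst_envelope(n + d, spec$fps, spec$burst_rate, spec$burst_dur_s)
  indep_env <- burst_envelope(n, spec$fps, spec$burst_rate, spec$burst_dur_s)
  core <- (d + 1L):(d + n)
  lead <- leader_env[core]
  foll <- spec$alpha * leader_env[core - d] + (1 - spec$alpha) * indep_env
  lead <- pmax(0, lead + rnorm(n, 0, spec$noise_sd))
  foll <- pmax(0, foll + rnorm(n, 0, spec$noise_sd))
  if (spec$delta_s >= 0)
    dyad_segment(lead, foll, spec$fps, phase, dyad_id)   # patient leads
  else
    dyad_segment(foll, lead, spec$fps, phase, dyad_id)   # therapist leads
}

#' Study-level simulation specification
#'
#' Conditions of a simulated pre/post-intervention study: a number of dyads,
#' one coupling per phase, and a therapy-readiness (VAS) distribution with a
#' strong ceiling effect. Defaults emulate a single-therapist study of 11
#' neurological in-patients: coupling strengthens after the intervention,
#' the therapist tends to lead before it and the patient after it, and VAS
#' readiness concentrates in the 82-100% range with one missing response.
#'
#' @param n_dyads Number of dyads (default 11).
#' @param pre_coupling,post_coupling [coupling_spec()]s for the pretalk and
#'   posttalk segments.
#' @param vas_mean,vas_sd Location and spread of the readiness distribution
#'   before truncation (defaults 94.2 and 6.23 percent).
#' @param vas_ceiling Upper truncation bound (default 100); draws above it
#'   pile up at the ceiling.
#' @param missing_vas_count How many dyads lack a VAS response (default 1).
#' @param seed Seed for the whole study draw.
#' @return A `study_spec` object.
#' @export
study_spec <- function(n_dyads = 11,
                       pre_coupling = coupling_spec(alpha = 0.2, delta_s = -0.5),
                       post_coupling = coupling_spec(alpha = 0.5, delta_s = 0.5),
                       vas_mean = 94.2, vas_sd = 6.23, vas_ceiling = 100,
                       missing_vas_count = 1, seed = NULL) {
  if (n_dyads < 2L) stop("parameter error: need at least 2 dyads")
  if (missing_vas_count >= n_dyads)
    stop("parameter error: missing_vas_count must be < n_dyads")
  structure(list(n_dyads = n_dyads, pre_coupling = pre_coupling,
                 post_coupling = post_coupling, vas_mean = vas_mean,
                 vas_sd = vas_sd, vas_ceiling = vas_ceiling,
                 missing_vas_count = missing_vas_count, seed = seed),
            class = "study_spec")
}

# lognormal draw matched to a target mean/sd by moment matching
rlnorm_match <- function(n, m, s) {
  sdlog <- sqrt(log(1 + (s / m)^2))
  rlnorm(n, meanlog = log(m) - sdlog^2 / 2, sdlog = sdlog)
}

#' Generate a full simulated study
#'
#' Draws `n_dyads` pre/post segment pairs with the specified couplings, a
#' session-metadata table with plausible segment durations, and a VAS
#' readiness vector from a ceiling-truncated normal distribution with the
#' configured number of missing responses.
#'
#' @param spec A [study_spec()].
#' @return List with `sessions` (data.frame: `dyad_id`, `pretalk`,
#'   `intervention`, `posttalk` as `hh:mm:ss`, `session_min`), `segments`
#'   (list per dyad with `$pre` and `$post` [dyad_segment()]s), `vas`
#'   (numeric vector with `NA` for missing), and `spec`.
#' @export
gen_study <- function(spec = study_spec()) {
  if (!inherits(spec, "study_spec")) stop("spec must be a study_spec")
  if (!is.null(spec$seed)) set.seed(spec$seed)
  ids <- sprintf("D%02d", seq_len(spec$n_dyads))
  segments <- lapply(ids, function(id) {
    pre <- spec$pre_coupling; pre$seed <- NULL
    post <- spec$post_coupling; post$seed <- NULL
    list(pre = gen_dyad(pre, "pretalk", id),
         post = gen_dyad(post, "posttalk", id))
  })
  names(segments) <- ids
  # plausible session structure: ~10 min pretalk, ~25 min intervention,
  # ~8 min posttalk; talk segments never shorter than the 2-min analysis span
  pre_s <- pmax(130, rlnorm_match(spec$n_dyads, 585, 400))
  int_s <- pmax(300, rlnorm_match(spec$n_dyads, 1535, 445))
  post_s <- pmax(130, rlnorm_match(spec$n_dyads, 505, 225))
  hms <- function(s) sprintf("%02d:%02d:%02d", floor(s / 3600),
                             floor((s %% 3600) / 60), round(s %% 60))
  sessions <- data.frame(
    dyad_id = ids, pretalk = hms(pre_s), intervention = hms(int_s),
    posttalk = hms(post_s),
    session_min = round((pre_s + int_s + post_s + runif(spec$n_dyads, 180, 600)) / 60, 2),
    stringsAsFactors = FALSE)
  vas <- pmin(spec$vas_ceiling, rnorm(spec$n_dyads, spec$vas_mean, spec$vas_sd))
  vas <- pmax(0, vas)
  if (spec$missing_vas_count > 0L)
    vas[sample.int(spec$n_dyads, spec$missing_vas_count)] <- NA_real_
  list(sessions = sessions, segments = segments, vas = vas, spec = spec)
}

#' Render synthetic frames of moving blobs
#'
#' Draws white square blobs on a black background moving along given pixel
#' trajectories, as a ground-truthed fixture for motion-energy extraction.
#' Blob parts leaving the frame are clipped with a warning. Alongside the
#' frames, per-step changed-pixel counts (whole frame, threshold 0) are
#' emitted as generation-side ground truth.
#'
#' @param trajectories List of data.frames with columns `x`, `y` (blob
#'   center per frame, 1-based pixel coordinates); all must have the same
#'   number of rows. An empty list yields black frames.
#' @param frame_size `c(height, width)` in pixels.
#' @param n_frames Number of frames; required when `trajectories` is empty,
#'   otherwise taken from the trajectory length.
#' @param fps Frame rate (default 30).
#' @param blob_half Half-width of the square blobs in pixels (default 3,
#'   giving a `7 x 7` blob).
#' @param intensity Blob intensity (default 255).
#' @return List with `frames` (a [frame_sequence()]) and `truth` (numeric
#'   vector of per-step changed-pixel counts).
#' @export
gen_frames <- function(trajectories, frame_size = c(40, 40), n_frames = NULL,
                       fps = 30, blob_half = 3, intensity = 255) {
  h <- frame_size[1L]; w <- frame_size[2L]
  if (length(trajectories)) {
    lens <- vapply(trajectories, nrow, integer(1L))
    if (length(unique(lens)) != 1L) stop("trajectories must have equal length")
    n_frames <- lens[1L]
  } else if (is.null(n_frames)) {
    stop("n_frames required when no trajectories are given")
  }
  if (n_frames < 2L) stop("need at least 2 frames")
  clipped <- FALSE
  a <- array(0, dim = c(h, w, n_frames))
  for (tr in trajectories) {
    for (t in seq_len(n_frames)) {
      xs <- (tr$x[t] - blob_half):(tr$x[t] + blob_half)
      ys <- (tr$y[t] - blob_half):(tr$y[t] + blob_half)
      if (any(xs < 1L | xs > w | ys < 1L | ys > h)) clipped <- TRUE
      xs <- xs[xs >= 1L & xs <= w]
      ys <- ys[ys >= 1L & ys <= h]
      if (length(xs) && length(ys)) a[ys, xs, t] <- intensity
    }
  }
  if (clipped) warning("blob partially left the frame; clipped")
  p <- matrix(a, ncol = n_frames)
  truth <- colSums(p[, -1L, drop = FALSE] != p[, -n_frames, drop = FALSE])
  list(frames = frame_sequence(a, fps), truth = as.numeric(truth))
}

#' Trajectory whose motion energy tracks a driving series
#'
#' Builds a horizontal bouncing trajectory whose per-step displacement is
#' proportional to a driving movement series, so the changed-pixel count of
#' the rendered blob is (up to integer rounding) proportional to the series.
#' Displacements are capped at the blob width, where the energy response
#' would saturate.
#'
#' @param series Non-negative driving series; the trajectory has
#'   `length(series) + 1` frames.
#' @param x_range `c(min, max)` horizontal blob-center range to bounce in.
#' @param y Fixed vertical blob-center position.
#' @param gain Pixels of displacement per unit of the series; default scales
#'   the series maximum to `max_step`.
#' @param max_step Largest allowed displacement in pixels.
#' @return data.frame with columns `x`, `y`, one row per frame.
#' @export
trajectory_from_series <- function(series, x_range, y, gain = NULL,
                                   max_step = diff(x_range)) {
  if (any(series < 0)) stop("driving series must be non-negative")
  if (is.null(gain)) gain <- if (max(series) > 0) max_step / max(series) else 0
  steps <- pmin(round(gain * series), max_step)
  x <- numeric(length(series) + 1L)
  x[1L] <- x_range[1L]
  dir <- 1
  for (t in seq_along(steps)) {
    nxt <- x[t] + dir * steps[t]
    if (nxt > x_range[2L] || nxt < x_range[1L]) {
      dir <- -dir
      nxt <- x[t] + dir * steps[t]
      nxt <- min(max(nxt, x_range[1L]), x_range[2L])
    }
    x[t + 1L] <- nxt
  }
  data.frame(x = x, y = rep(y, length(x)))
}
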