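#' Synchrony analysis parameters
#'
#' Parameters of the windowed lagged cross-correlation. Defaults follow the
#' standard configuration for 2-minute conversational segments: 10 s
#' non-overlapping windows, lags up to +/-2 s, light 0.5 s moving-average
#' smoothing, no standardization. Two rules of thumb are enforced: a window
#' must contain at least 50 samples, and must be at least 4 times the
#' maximum lag, so that each window-level correlation has enough effective
#' length relative to the shift.
#'
#' @param window_s Window length in seconds (default 10).
#' @param max_lag_s Maximum absolute lag in seconds (default 2).
#' @param smoothing_s Width of the centered moving-average applied to each
#'   series before correlation, in seconds; 0 disables smoothing.
#' @param standardize Z-score each series before correlation? Pearson
#'   correlations are unaffected; provided for inspecting preprocessed
#'   series on a common scale.
#' @param fisher_clip_epsilon Correlations are clipped to
#'   `+/-(1 - epsilon)` before the Fisher transform, which diverges at
#'   `|r| = 1`.
#' @param fps Sampling rate of the series in Hz.
#' @return A `sync_params` object.
#' @export
sync_params <- function(window_s = 10, max_lag_s = 2, smoothing_s = 0.5,
                        standardize = FALSE, fisher_clip_epsilon = 1e-6,
                        fps = 30) {
  if (window_s <= 0 || max_lag_s < 0 || smoothing_s < 0 || fps <= 0)
    stop("parameter error: window, lag, smoothing and fps must be non-negative (fps, window positive)")
  if (fisher_clip_epsilon <= 0 || fisher_clip_epsilon >= 1)
    stop("parameter error: fisher_clip_epsilon must be in (0, 1)")
  if (round(window_s * fps) < 50)
    stop("parameter error: window must contain at least 50 samples")
  if (max_lag_s > 0 && window_s < 4 * max_lag_s)
    stop("parameter error: window must be at least 4-5 times the maximum lag")
  structure(list(window_s = window_s, max_lag_s = max_lag_s,
                 overlap_s = 0, smoothing_s = smoothing_s,
                 standardize = standardize,
                 fisher_clip_epsilon = fisher_clip_epsilon, fps = fps),
            class = "sync_params")
}

#' Dyadic movement segment
#'
#' Aligned patient and therapist whole-body movement series for one labeled
#' conversational segment of a session.
#'
#' @param patient,therapist Equal-length non-negative numeric vectors.
#' @param fps Sampling rate in Hz.
#' @param phase Segment label, `"pretalk"` or `"posttalk"`.
#' @param dyad_id Identifier of the patient-therapist pair.
#' @return A `dyad_segment` object.
#' @export
dyad_segment <- function(patient, therapist, fps = 30, phase = "pretalk",
                         dyad_id = NA_character_) {
  if (length(patient) != length(therapist))
    stop("patient and therapist series must have equal length")
  if (fps <= 0) stop("fps must be positive")
  structure(list(patient = as.numeric(patient),
                 therapist = as.numeric(therapist),
                 fps = fps, phase = phase, dyad_id = dyad_id,
                 duration_s = length(patient) / fps),
            class = "dyad_segment")
}

#' @export
print.dyad_segment <- function(x, ...) {
  cat(sprintf("<dyad_segment> %s %s: %d samples at %g fps (%.1f s)\n",
              x$dyad_id, x$phase, length(x$patient), x$fps, x$duration_s))
  invisible(x)
}

#' Cut an analysis segment out of a recording
#'
#' Takes the contiguous slice of `duration_s` seconds that ends at
#' (`side = "before"`) or starts at (`side = "after"`) a boundary, e.g. the
#' onset or offset of an intervention. The boundary is the number of samples
#' elapsed: `side = "before"` returns samples `boundary - n + 1 ..
#' boundary`, `side = "after"` returns `boundary + 1 .. boundary + n`.
#'
#' @param series Numeric vector sampled at `fps`.
#' @param boundary Boundary position in samples (use `boundary_s` for
#'   seconds).
#' @param side `"before"` or `"after"` the boundary.
#' @param duration_s Slice length in seconds (default 120).
#' @param fps Sampling rate in Hz.
#' @param boundary_s Boundary position in seconds (overrides `boundary`).
#' @return Numeric vector of `duration_s * fps` samples.
#' @export
extract_segment <- function(series, boundary, side = c("before", "after"),
                            duration_s = 120, fps = 30, boundary_s = NULL) {
  side <- match.arg(side)
  if (!is.null(boundary_s)) boundary <- round(boundary_s * fps)
  n <- round(duration_s * fps)
  idx <- if (side == "before") (boundary - n + 1L):boundary
         else (boundary + 1L):(boundary + n)
  if (idx[1L] < 1L || idx[length(idx)] > length(series))
    stop(sprintf("range error: requested %s-slice [%d, %d] exceeds recording of %d samples",
                 side, idx[1L], idx[length(idx)], length(series)))
  series[idx]
}

# centered moving average with window shrinking at the edges
moving_average <- function(x, width) {
  if (width <= 1L) return(x)
  n <- length(x)
  h <- (width - 1L) %/% 2L
  hi <- width - 1L - h          # asymmetric split for even widths
  cs <- c(0, cumsum(x))
  lo_i <- pmax(seq_len(n) - h, 1L)
  hi_i <- pmin(seq_len(n) + hi, n)
  (cs[hi_i + 1L] - cs[lo_i]) / (hi_i - lo_i + 1L)
}

#' Preprocess a dyadic segment
#'
#' Optional centered moving-average smoothing (edge windows shrink) and
#' optional per-series standardization, applied to both members. Length is
#' preserved; with `smoothing_s = 0` and `standardize = FALSE` this is the
#' identity.
#'
#' @param segment A [dyad_segment()].
#' @param params A [sync_params()].
#' @return A preprocessed [dyad_segment()].
#' @export
preprocess_segment <- function(segment, params = sync_params(fps = segment$fps)) {
  w <- round(params$smoothing_s * params$fps)
  p <- moving_average(segment$patient, w)
  t <- moving_average(segment$therapist, w)
  if (isTRUE(params$standardize)) {
    zs <- function(v) if (sd(v) > 0) (v - mean(v)) / sd(v) else v - mean(v)
    p <- zs(p); t <- zs(t)
  }
  out <- segment
  out$patient <- p
  out$therapist <- t
  out
}

#' Windowed lagged cross-correlation of a dyadic segment
#'
#' Splits the segment into non-overlapping windows and computes, for every
#' window and every integer lag in `[-max_lag, +max_lag]` samples, the
#' Pearson correlation between the patient window and the therapist window
#' shifted by the lag, then Fisher-Z transforms it. The shift is sourced
#' from samples adjacent to the window, so every correlation uses
#' full-length vectors; cells whose shifted window would run past the end
#' of the recording are `NA`.
#'
#' Lag-sign convention: at lag `l > 0` the therapist's samples are paired
#' with earlier patient samples, i.e. the patient's movement precedes the
#' therapist's, so positive lags contribute to patient leading and negative
#' lags to therapist leading. The convention is stored in the result and
#' pinned by the member-swap symmetry: swapping patient and therapist maps
#' `z[w, l]` to `z[w, -l]` exactly.
#'
#' Windows with (numerically) zero variance in either member carry no
#' correlation evidence; they are scored `z = 0` and flagged degenerate.
#'
#' @param segment A [dyad_segment()] (already preprocessed, or pass
#'   `preprocess = TRUE`).
#' @param params A [sync_params()].
#' @param preprocess Apply [preprocess_segment()] first? Default `TRUE`.
#' @return A `crosscorr_matrix` object: `z` (windows x lags matrix of
#'   Fisher-Z correlations), `lags` (sample offsets), `window_starts`,
#'   `degenerate` (logical matrix), `lag_convention`.
#' @export
windowed_lagged_crosscorr <- function(segment, params = sync_params(fps = segment$fps),
                                      preprocess = TRUE) {
  if (abs(params$fps - segment$fps) > 1e-9)
    stop("parameter error: params$fps does not match the segment fps")
  if (preprocess) segment <- preprocess_segment(segment, params)
  W <- round(params$window_s * params$fps)
  L <- round(params$max_lag_s * params$fps)
  N <- length(segment$patient)
  if (N < W) stop("segment shorter than one window")
  x <- segment$patient - mean(segment$patient)
  y <- segment$therapist - mean(segment$therapist)
  res <- .wlcc_core(x, y, W, L, 1e-13)
  eps <- params$fisher_clip_epsilon
  z <- atanh(pmin(pmax(res$r, -(1 - eps)), 1 - eps))
  structure(list(z = z, lags = -L:L,
                 window_starts = (seq_len(N %/% W) - 1L) * W + 1L,
                 degenerate = res$degenerate,
                 fps = params$fps, params = params,
                 phase = segment$phase, dyad_id = segment$dyad_id,
                 lag_convention = "positive lag = patient precedes (patient leading)"),
            class = "crosscorr_matrix")
}

#' @export
print.crosscorr_matrix <- function(x, ...) {
  cat(sprintf("<crosscorr_matrix> %d windows x %d lags (+/-%d samples), %d degenerate, %d out-of-range\n",
              nrow(x$z), ncol(x$z), max(x$lags), sum(x$degenerate), sum(is.na(x$z))))
  cat(" ", x$lag_convention, "\n")
  invisible(x)
}

#' Summarize a cross-correlation matrix into synchrony measures
#'
#' Averages absolute Fisher-Z correlations `|z|`: over all windows and lags
#' (the grand average), at lag zero only, over strictly negative lags
#' (therapist leading) and strictly positive lags (patient leading), plus
#' the leading difference. Lag zero belongs to neither leading component.
#' `NA` cells (shifted window out of range) are excluded; degenerate cells
#' count as 0.
#'
#' @param ccm A `crosscorr_matrix` from [windowed_lagged_crosscorr()].
#' @return A `synchrony_result`: list with `zccf_all_lags`, `zccf_lag_zero`,
#'   `therapist_lead`, `patient_lead`, `tlead_minus_plead`, `n_windows`,
#'   `n_degenerate`, `phase`, `dyad_id`.
#' @export
summarize_synchrony <- function(ccm) {
  az <- abs(ccm$z)
  neg <- ccm$lags < 0
  pos <- ccm$lags > 0
  res <- list(
    zccf_all_lags = mean(az, na.rm = TRUE),
    zccf_lag_zero = mean(az[, ccm$lags == 0], na.rm = TRUE),
    therapist_lead = mean(az[, neg, drop = FALSE], na.rm = TRUE),
    patient_lead = mean(az[, pos, drop = FALSE], na.rm = TRUE))
  res$tlead_minus_plead <- res$therapist_lead - res$patient_lead
  res$n_windows <- nrow(ccm$z)
  res$n_degenerate <- sum(ccm$degenerate)
  res$phase <- ccm$phase
  res$dyad_id <- ccm$dyad_id
  structure(res, class = "synchrony_result")
}

#' @export
print.synchrony_result <- function(x, ...) {
  cat(sprintf("<synchrony_result> %s %s\n", x$dyad_id, x$phase))
  cat(sprintf("  |zCCF| all lags %.4f | lag zero %.4f | T-lead %.4f | P-lead %.4f | Tlead-Plead %+.4f\n",
              x$zccf_all_lags, x$zccf_lag_zero, x$therapist_lead,
              x$patient_lead, x$tlead_minus_plead))
  if (x$n_degenerate > 0)
    cat(sprintf("  %d degenerate (zero-variance) window cells scored 0\n", x$n_degenerate))
  invisible(x)
}

#' One-call synchrony profile of a dyadic segment
#'
#' Convenience wrapper: preprocess, cross-correlate, summarize.
#'
#' @inheritParams windowed_lagged_crosscorr
#' @return A `synchrony_result`, see [summarize_synchrony()].
#' @export
dyad_synchrony <- function(segment, params = sync_params(fps = segment$fps),
                           preprocess = TRUE) {
  summarize_synchrony(windowed_lagged_crosscorr(segment, params, preprocess))
}

#' Tabulate synchrony results
#'
#' @param results A list of `synchrony_result` objects.
#' @return A data.frame with one row per result and the five synchrony
#'   measures as columns.
#' @export
synchrony_table <- function(results) {
  do.call(rbind, lapply(results, function(r)
    data.frame(dyad_id = r$dyad_id, phase = r$phase,
               zccf_all_lags = r$zccf_all_lags,
               zccf_lag_zero = r$zccf_lag_zero,
               therapist_lead = r$therapist_lead,
               patient_lead = r$patient_lead,
               tlead_minus_plead = r$tlead_minus_plead,
               n_degenerate = r$n_degenerate,
               stringsAsFactors = FALSE)))
}
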