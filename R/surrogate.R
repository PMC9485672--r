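#' A pool of labeled dyadic recordings
#'
#' Collects the genuine recordings from which surrogate dyads are built:
#' each entry is a [dyad_segment()] labeled by `(dyad_id, phase)`. All
#' recordings must share sampling rate and duration; labels must be unique.
#' The three standard pools are both phases together, pretalk only, and
#' posttalk only.
#'
#' @param segments List of [dyad_segment()] objects.
#' @param phases Optional subset of phases to keep, e.g. `"pretalk"`.
#' @return A `segment_pool` object.
#' @export
segment_pool <- function(segments, phases = NULL) {
  if (!is.null(phases))
    segments <- Filter(function(s) s$phase %in% phases, segments)
  if (length(segments) == 0L) stop("insufficient-pool error: empty pool")
  keys <- vapply(segments, function(s) paste(s$dyad_id, s$phase), "")
  if (anyDuplicated(keys)) stop("duplicate (dyad_id, phase) labels in pool")
  fps <- vapply(segments, `[[`, numeric(1L), "fps")
  len <- vapply(segments, function(s) length(s$patient), integer(1L))
  if (length(unique(fps)) != 1L || length(unique(len)) != 1L)
    stop("all recordings in a pool must share fps and duration")
  structure(list(segments = segments, keys = keys, m = length(segments),
                 phases_included = unique(vapply(segments, `[[`, "", "phase"))),
            class = "segment_pool")
}

#' @export
print.segment_pool <- function(x, ...) {
  cat(sprintf("<segment_pool> %d recordings (%s)\n", x$m,
              paste(x$phases_included, collapse = " + ")))
  invisible(x)
}

#' Enumerate the surrogate (pseudosynchrony) dyads of a pool
#'
#' Builds every cross-recording recombination: for each ordered pair of
#' distinct recordings `(i, j)` the patient series of `i` is paired with the
#' therapist series of `j`, and — the second role crossing — the therapist
#' series of `i` (cast as patient) is paired with the patient series of `j`
#' (cast as therapist). This yields exactly `m * (m - 1) * 2` surrogate
#' dyads for a pool of `m` recordings; no recording is ever paired with
#' itself, and enumeration order is deterministic. Recombination across
#' recordings destroys any genuine moment-to-moment coupling, so the
#' synchrony of these pairs is the chance ("pseudosynchrony") level.
#'
#' @param pool A [segment_pool()] with at least 2 recordings.
#' @param subsample Optional number of surrogate dyads to draw from the full
#'   enumeration, without replacement.
#' @param seed Seed for the subsample draw (required when `subsample` is
#'   given).
#' @return A `surrogate_pool` object whose `pairs` data.frame has one row
#'   per surrogate dyad (`i`, `j`, `series_i`, `series_j`).
#' @export
build_surrogate_pool <- function(pool, subsample = NULL, seed = NULL) {
  if (pool$m < 2L) stop("insufficient-pool error: need at least 2 recordings")
  idx <- expand.grid(j = seq_len(pool$m), i = seq_len(pool$m))[, c("i", "j")]
  idx <- idx[idx$i != idx$j, , drop = FALSE]
  pairs <- rbind(
    data.frame(idx, series_i = "patient", series_j = "therapist",
               stringsAsFactors = FALSE),
    data.frame(idx, series_i = "therapist", series_j = "patient",
               stringsAsFactors = FALSE))
  rownames(pairs) <- NULL
  if (!is.null(subsample)) {
    if (is.null(seed)) stop("subsampling requires an explicit seed")
    if (subsample > nrow(pairs)) stop("subsample exceeds full enumeration")
    set.seed(seed)
    pairs <- pairs[sample.int(nrow(pairs), subsample), , drop = FALSE]
  }
  structure(list(pool = pool, pairs = pairs, n_surrogates = nrow(pairs)),
            class = "surrogate_pool")
}

#' @export
print.surrogate_pool <- function(x, ...) {
  cat(sprintf("<surrogate_pool> %d surrogate dyads from %d recordings\n",
              x$n_surrogates, x$pool$m))
  invisible(x)
}

#' Pseudosynchrony distribution of a surrogate pool
#'
#' Applies the identical synchrony computation used for genuine dyads to
#' every surrogate dyad. Per-series preprocessing (smoothing) is done once
#' per recording and reused across recombinations, which is equivalent to
#' preprocessing every surrogate pair because smoothing acts on each series
#' independently.
#'
#' @param spool A `surrogate_pool` from [build_surrogate_pool()].
#' @param params A [sync_params()].
#' @return List of `synchrony_result` objects, one per surrogate dyad, in
#'   enumeration order.
#' @export
pseudosynchrony_distribution <- function(spool, params = NULL) {
  segs <- spool$pool$segments
  if (is.null(params)) params <- sync_params(fps = segs[[1L]]$fps)
  pre <- lapply(segs, preprocess_segment, params = params)
  keys <- spool$pool$keys
  lapply(seq_len(nrow(spool$pairs)), function(k) {
    p <- spool$pairs[k, ]
    seg <- dyad_segment(pre[[p$i]][[p$series_i]], pre[[p$j]][[p$series_j]],
                        fps = params$fps, phase = "surrogate",
                        dyad_id = sprintf("%s[%s] x %s[%s]",
                                          keys[p$i], p$series_i,
                                          keys[p$j], p$series_j))
    dyad_synchrony(seg, params, preprocess = FALSE)
  })
}

# Cohen's d with pooled SD (n - 1 denominators), a minus b
cohens_d <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  if (n1 < 2L || n2 < 2L) stop("need >= 2 values per group for d")
  sp2 <- ((n1 - 1) * var(a) + (n2 - 1) * var(b)) / (n1 + n2 - 2)
  if (sp2 <= 0) stop("undefined-d error: zero pooled SD")
  (mean(a) - mean(b)) / sqrt(sp2)
}

#' Compare genuine synchrony against its pseudosynchrony null
#'
#' Two-group comparison of genuine dyads' synchrony values against the
#' surrogate distribution: Welch's two-sample t-test (no equal-variance
#' assumption) and Cohen's d with pooled SD, both reported as real minus
#' pseudo, so positive d means genuine synchrony above chance.
#'
#' @param real Numeric vector of genuine synchrony values, or a list of
#'   `synchrony_result` objects.
#' @param pseudo Numeric vector or list of `synchrony_result` objects from
#'   the surrogate pool.
#' @param measure Which synchrony measure to extract from result lists
#'   (default `"zccf_all_lags"`).
#' @return A `surrogate_comparison`: list with `effect_size_d`, `p_value`,
#'   `statistic` (Welch t), `df`, `n_real`, `n_pseudo`, `mean_real`,
#'   `mean_pseudo`, `measure`.
#' @export
compare_real_vs_pseudo <- function(real, pseudo, measure = "zccf_all_lags") {
  pull <- function(v) if (is.list(v)) vapply(v, `[[`, numeric(1L), measure) else v
  a <- pull(real); b <- pull(pseudo)
  if (length(a) == 0L || length(b) == 0L) stop("both groups must be nonempty")
  d <- cohens_d(a, b)                     # validates a positive pooled SD
  tt <- stats::t.test(a, b, var.equal = FALSE)
  structure(list(effect_size_d = d,
                 p_value = tt$p.value,
                 statistic = unname(tt$statistic),
                 df = unname(tt$parameter),
                 n_real = length(a), n_pseudo = length(b),
                 mean_real = mean(a), mean_pseudo = mean(b),
                 measure = measure),
            class = "surrogate_comparison")
}

#' @export
print.surrogate_comparison <- function(x, ...) {
  cat(sprintf("<surrogate_comparison> %s: real %.4f (n=%d) vs pseudo %.4f (n=%d)\n",
              x$measure, x$mean_real, x$n_real, x$mean_pseudo, x$n_pseudo))
  if (identical(x$method, "permutation")) {
    cat(sprintf("  permutation p = %.4g (%d pairings), d = %.3f, Welch t = %.3f (Welch p = %.4g)\n",
                x$p_value, x$n_perm, x$effect_size_d, x$welch_t, x$welch_p))
  } else {
    cat(sprintf("  Welch t = %.3f (df %.1f), p = %.4g, d = %.3f\n",
                x$statistic, x$df, x$p_value, x$effect_size_d))
  }
  invisible(x)
}

#' Permutation test of genuine synchrony against pseudosynchrony
#'
#' Exactly calibrated significance for the real-vs-pseudo question. The
#' synchrony values of all patient-series x therapist-series pairings of a
#' pool form an `m x m` matrix whose diagonal holds the genuine dyads; with
#' no genuine coupling the diagonal mean is exchangeable with the mean over
#' any random pairing (a random transversal of the matrix), because the
#' member series are then mutually independent. The one-sided p-value is
#' the Monte Carlo rank of the genuine-pairing mean among `n_perm` random
#' permutations (with the `+1` correction). A naive two-sample test on the
#' same values is conservative here, because the surrogate values reuse the
#' same few series and are therefore correlated with the genuine values;
#' the permutation test is immune to that dependence. Cohen's d against the
#' full surrogate enumeration and the Welch statistic are reported
#' alongside as descriptive effect sizes.
#'
#' @param pool A [segment_pool()] of genuine recordings.
#' @param params A [sync_params()].
#' @param phases Which phase's genuine dyads form the tested group
#'   (default: all phases in the pool). The permutation always runs over
#'   the whole pool, mirroring the pool definitions.
#' @param n_perm Number of random pairings (default 2000).
#' @param measure Synchrony measure to test (default `"zccf_all_lags"`).
#' @param subsample,subsample_seed Optionally evaluate only a random subset
#'   of the surrogate enumeration (for very large pools); the permutation
#'   p-value is then unavailable and the Welch p is reported instead.
#' @return A `surrogate_comparison` with `p_value` from the permutation
#'   test, plus `welch_p`, `welch_t`, `effect_size_d`, group means and
#'   sizes.
#' @export
pseudosynchrony_test <- function(pool, params = NULL, phases = NULL,
                                 n_perm = 2000, measure = "zccf_all_lags",
                                 subsample = NULL, subsample_seed = NULL) {
  if (is.null(params)) params <- sync_params(fps = pool$segments[[1L]]$fps)
  m <- pool$m
  if (m < 2L) stop("insufficient-pool error: need at least 2 recordings")
  spool <- build_surrogate_pool(pool, subsample = subsample,
                                seed = subsample_seed)
  pseudo_res <- pseudosynchrony_distribution(spool, params)
  pseudo <- vapply(pseudo_res, `[[`, numeric(1L), measure)
  real_res <- lapply(pool$segments, dyad_synchrony, params = params)
  real_all <- vapply(real_res, `[[`, numeric(1L), measure)
  # patient x therapist value matrix: diagonal genuine, off-diagonal from
  # the patient->therapist half of the surrogate enumeration
  V <- matrix(NA_real_, m, m)
  diag(V) <- real_all
  half <- spool$pairs$series_i == "patient"
  V[cbind(spool$pairs$i[half], spool$pairs$j[half])] <- pseudo[half]
  target <- if (is.null(phases)) seq_len(m)
            else which(vapply(pool$segments, `[[`, "", "phase") %in% phases)
  if (length(target) == 0L) stop("no recordings in the requested phase(s)")
  obs <- mean(real_all[target])
  wl <- compare_real_vs_pseudo(real_all[target], pseudo, measure = measure)
  if (!is.null(subsample)) {
    out <- unclass(wl)
    out$method <- "welch (subsampled enumeration)"
    out$welch_t <- out$statistic; out$welch_p <- out$p_value
    return(structure(out, class = "surrogate_comparison"))
  }
  perm_means <- vapply(seq_len(n_perm), function(k) {
    sigma <- sample.int(m)
    mean(V[cbind(target, sigma[target])])
  }, numeric(1L))
  p_perm <- (1 + sum(perm_means >= obs)) / (n_perm + 1)
  structure(list(p_value = p_perm, n_perm = n_perm,
                 effect_size_d = wl$effect_size_d,
                 welch_t = wl$statistic, welch_p = wl$p_value,
                 statistic = obs, null_mean = mean(perm_means),
                 n_real = length(target), n_pseudo = length(pseudo),
                 mean_real = obs, mean_pseudo = mean(pseudo),
                 measure = measure, method = "permutation"),
            class = "surrogate_comparison")
}

#' Effect size of synchrony above chance across window sizes
#'
#' Recomputes genuine and surrogate synchrony for several window lengths on
#' the same data and reports the real-vs-pseudo effect size for each,
#' supporting the choice of window size.
#'
#' @param pool A [segment_pool()] of genuine recordings.
#' @param spool A `surrogate_pool` built from (a pool over) the same data.
#' @param window_list Window lengths in seconds (default `c(10, 20, 30)`).
#' @param params Base [sync_params()]; everything but `window_s` is reused.
#' @return data.frame with one row per window size: `window_s`, `d`, `p`,
#'   `statistic`, `n_real`, `n_pseudo`.
#' @export
window_size_sweep <- function(pool, spool, window_list = c(10, 20, 30),
                              params = NULL) {
  if (is.null(params)) params <- sync_params(fps = pool$segments[[1L]]$fps)
  rows <- lapply(window_list, function(w) {
    pw <- sync_params(window_s = w, max_lag_s = params$max_lag_s,
                      smoothing_s = params$smoothing_s,
                      standardize = params$standardize,
                      fisher_clip_epsilon = params$fisher_clip_epsilon,
                      fps = params$fps)
    real <- lapply(pool$segments, dyad_synchrony, params = pw)
    pseudo <- pseudosynchrony_distribution(spool, pw)
    cmp <- compare_real_vs_pseudo(real, pseudo)
    data.frame(window_s = w, d = cmp$effect_size_d, p = cmp$p_value,
               statistic = cmp$statistic, n_real = cmp$n_real,
               n_pseudo = cmp$n_pseudo)
  })
  do.call(rbind, rows)
}
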