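test_that("segment extraction slices exactly and rejects out-of-range spans", {
  s <- seq_len(3600)
  expect_equal(extract_segment(s, 3600, "before", 120, 30), 1:3600)
  expect_error(extract_segment(rnorm(2000), 1000, "after", 120, 30),
               "range error")
  mid <- extract_segment(s, 1800, "before", 10, 30)
  aft <- extract_segment(s, 1800, "after", 10, 30)
  expect_equal(c(mid, aft), 1501:2100)       # adjacent, disjoint partition
  expect_equal(extract_segment(s, boundary_s = 60, side = "before",
                               duration_s = 10, fps = 30),
               extract_segment(s, 1800, "before", 10, 30))
})

test_that("preprocessing is the identity when disabled and matches the convolution oracle", {
  seg <- dyad_segment(rpois(600, 5), rpois(600, 5))
  p0 <- sync_params(smoothing_s = 0)
  expect_equal(preprocess_segment(seg, p0)$patient, seg$patient)
  # constant series unchanged by smoothing
  cs <- dyad_segment(rep(3, 600), rep(7, 600))
  sm <- preprocess_segment(cs, sync_params(smoothing_s = 0.5))
  expect_equal(sm$patient, rep(3, 600))
  # impulse vs brute-force moving average, including edges
  x <- numeric(300); x[150] <- 1; x[1] <- 2; x[300] <- 5
  seg2 <- dyad_segment(x, x)
  got <- preprocess_segment(seg2, sync_params(smoothing_s = 0.5))$patient
  expect_equal(got, oracle_moving_average(x, 15))
})

test_that("parameter invariants are enforced", {
  expect_error(sync_params(window_s = 1, fps = 30), "at least 50 samples")
  expect_error(sync_params(window_s = 10, max_lag_s = 4), "4-5 times")
  expect_error(sync_params(fisher_clip_epsilon = 0), "epsilon")
  expect_silent(sync_params(window_s = 10, max_lag_s = 2))
})

test_that("identical members give clipped-perfect lag-zero correlation", {
  set.seed(201)
  v <- rpois(3600, 6) + runif(3600)
  seg <- dyad_segment(v, v)
  p <- sync_params()
  ccm <- windowed_lagged_crosscorr(seg, p)
  lag0 <- ccm$z[, ccm$lags == 0]
  expect_equal(lag0, rep(atanh(1 - 1e-6), 12))
  expect_true(all(abs(ccm$z) <= atanh(1 - 1e-6) + 1e-12, na.rm = TRUE))
  expect_equal(nrow(ccm$z), 12L)                   # floor(120 s / 10 s)
  expect_equal(range(ccm$lags), c(-60, 60))        # inclusive endpoints
})

test_that("constant members are degenerate, scoring zero everywhere", {
  seg <- dyad_segment(rep(2, 3600), rep(5, 3600))
  ccm <- windowed_lagged_crosscorr(seg, sync_params())
  expect_true(all(ccm$degenerate[!is.na(ccm$z)]))
  s <- summarize_synchrony(ccm)
  expect_equal(s$zccf_all_lags, 0)
  expect_equal(s$zccf_lag_zero, 0)
  expect_equal(s$tlead_minus_plead, 0)
  expect_gt(s$n_degenerate, 0)
})

test_that("cross-correlations match the naive triple-loop oracle", {
  set.seed(202)
  seg <- sim_segment(alpha = 0.5, delta_s = 0.7)
  p <- sync_params()
  pp <- preprocess_segment(seg, p)
  ccm <- windowed_lagged_crosscorr(seg, p)
  nv <- oracle_wlcc(pp$patient, pp$therapist, 300, 60)
  expect_equal(is.na(ccm$z), is.na(nv))
  expect_lt(max(abs(tanh(ccm$z) - nv), na.rm = TRUE), 1e-10)
})

test_that("member swap exchanges the leading components exactly", {
  set.seed(203)
  seg <- sim_segment(alpha = 0.6, delta_s = 1)
  p <- sync_params()
  a <- dyad_synchrony(seg, p)
  swapped <- dyad_segment(seg$therapist, seg$patient, seg$fps)
  b <- dyad_synchrony(swapped, p)
  expect_equal(a$therapist_lead, b$patient_lead)
  expect_equal(a$patient_lead, b$therapist_lead)
  expect_equal(a$tlead_minus_plead, -b$tlead_minus_plead)
  expect_equal(a$zccf_all_lags, b$zccf_all_lags)
  expect_equal(a$zccf_lag_zero, b$zccf_lag_zero)
})

test_that("synchrony is invariant to positive rescaling of either member", {
  set.seed(204)
  seg <- sim_segment(alpha = 0.4)
  p <- sync_params()
  a <- dyad_synchrony(seg, p)
  seg2 <- seg; seg2$patient <- seg2$patient * 3.7
  b <- dyad_synchrony(seg2, p)
  expect_equal(a$zccf_all_lags, b$zccf_all_lags, tolerance = 1e-12)
  expect_equal(a$tlead_minus_plead, b$tlead_minus_plead, tolerance = 1e-12)
})

test_that("a delayed copy is detected as the leader with the right sign", {
  set.seed(205)
  # follower = leader delayed by 1 s with strong coupling; patient leads
  seg <- sim_segment(alpha = 0.9, delta_s = 1, seed = 205)
  p <- sync_params()
  ccm <- windowed_lagged_crosscorr(seg, p)
  s <- summarize_synchrony(ccm)
  expect_gt(s$patient_lead, s$therapist_lead)
  expect_lt(s$tlead_minus_plead, 0)
  # and the oracle matrix agrees about where the correlation mass sits
  pp <- preprocess_segment(seg, p)
  nv <- oracle_wlcc(pp$patient, pp$therapist, 300, 60)
  lagmean <- colMeans(abs(atanh(pmin(pmax(nv, -(1 - 1e-6)), 1 - 1e-6))),
                      na.rm = TRUE)
  lags <- -60:60
  expect_gt(mean(lagmean[lags > 0]), mean(lagmean[lags < 0]))
})

test_that("the grand average sits inside the span of its components", {
  set.seed(206)
  for (i in 1:5) {
    s <- dyad_synchrony(sim_segment(alpha = runif(1), delta_s = runif(1, -1, 1)),
                        sync_params())
    comps <- c(s$therapist_lead, s$patient_lead, s$zccf_lag_zero)
    expect_gte(s$zccf_all_lags, min(comps))
    expect_lte(s$zccf_all_lags, max(comps))
    expect_gte(s$zccf_lag_zero, 0)
  }
})

test_that("equal-role dyads show no systematic leading", {
  set.seed(207)
  diffs <- replicate(200, dyad_synchrony(
    gen_dyad(coupling_spec(alpha = 0.5, delta_s = 0, duration_s = 60)),
    sync_params())$tlead_minus_plead)
  expect_lt(abs(mean(diffs)) / (sd(diffs) / sqrt(length(diffs))), 4)
})
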