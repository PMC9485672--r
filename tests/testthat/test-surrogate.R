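# tiny constant-free recordings for combinatorial tests
toy_pool <- function(m, phases = "pretalk") {
  segs <- list()
  for (ph in phases) for (i in seq_len(m)) {
    set.seed(1000 + i + 100 * match(ph, phases))
    segs <- c(segs, list(dyad_segment(rnorm(300) + 2, rnorm(300) + 2,
                                      fps = 30, phase = ph,
                                      dyad_id = sprintf("D%02d", i))))
  }
  segment_pool(segs)
}

test_that("the surrogate enumeration has size m(m-1)*2 with no self-pairings or duplicates", {
  for (m in c(2, 3, 5, 8)) {
    sp <- build_surrogate_pool(toy_pool(m))
    expect_equal(sp$n_surrogates, m * (m - 1) * 2)
    expect_true(all(sp$pairs$i != sp$pairs$j))
    key <- with(sp$pairs, paste(i, series_i, j, series_j))
    expect_equal(anyDuplicated(key), 0L)
  }
  expect_error(build_surrogate_pool(toy_pool(1)), "insufficient-pool")
})

test_that("pool sizes match the two-phase layout and subsampling is seeded", {
  expect_equal(build_surrogate_pool(toy_pool(11))$n_surrogates, 220)
  expect_equal(build_surrogate_pool(toy_pool(11, c("pretalk", "posttalk")))$n_surrogates, 924)
  sp1 <- build_surrogate_pool(toy_pool(5), subsample = 10, seed = 9)
  sp2 <- build_surrogate_pool(toy_pool(5), subsample = 10, seed = 9)
  expect_identical(sp1$pairs, sp2$pairs)
  expect_equal(sp1$n_surrogates, 10L)
  expect_error(build_surrogate_pool(toy_pool(5), subsample = 10), "seed")
})

test_that("a pool of identical recordings gives surrogate synchrony equal to the genuine value", {
  set.seed(301)
  base <- gen_dyad(coupling_spec(alpha = 0.7, duration_s = 30))
  segs <- lapply(1:3, function(i)
    dyad_segment(base$patient, base$therapist, 30, "pretalk", paste0("D", i)))
  pool <- segment_pool(segs)
  p <- sync_params(window_s = 10, max_lag_s = 2)
  genuine <- dyad_synchrony(segs[[1]], p)$zccf_all_lags
  pseudo <- pseudosynchrony_distribution(build_surrogate_pool(pool), p)
  expect_length(pseudo, 12L)            # 3 * 2 * 2
  vals <- vapply(pseudo, `[[`, numeric(1), "zccf_all_lags")
  # |zCCF| is swap-invariant, so the role-crossed half matches too
  expect_true(all(abs(vals - genuine) < 1e-12))
})

test_that("pseudosynchrony with preprocessing equals direct recomputation per pair", {
  set.seed(302)
  pool <- sim_pool(3, alpha = 0.3, duration_s = 30)
  p <- sync_params()
  sp <- build_surrogate_pool(pool)
  dist <- pseudosynchrony_distribution(sp, p)
  k <- 5
  pr <- sp$pairs[k, ]
  seg <- dyad_segment(pool$segments[[pr$i]][[pr$series_i]],
                      pool$segments[[pr$j]][[pr$series_j]], fps = 30)
  direct <- dyad_synchrony(seg, p)       # preprocesses the pair directly
  expect_equal(dist[[k]]$zccf_all_lags, direct$zccf_all_lags, tolerance = 1e-12)
})

test_that("Cohen's d follows the pooled-SD formula and degenerates sanely", {
  a <- c(1.0, 1.2, 0.9, 1.1)
  b <- c(0.4, 0.5, 0.45)
  sp <- sqrt((3 * var(a) + 2 * var(b)) / 5)
  cmp <- compare_real_vs_pseudo(a, b)
  expect_equal(cmp$effect_size_d, (mean(a) - mean(b)) / sp, tolerance = 1e-12)
  expect_equal(compare_real_vs_pseudo(c(1, 2, 3), c(1, 2, 3))$effect_size_d, 0)
  sigma <- 0.01
  jit <- c(-1, 1) * sigma / sqrt(2)      # sample SD = sigma in each group
  d <- compare_real_vs_pseudo(c(1, 1) + jit, c(0, 0) + jit)$effect_size_d
  expect_equal(d, 1 / sigma, tolerance = 1e-9)
  expect_error(compare_real_vs_pseudo(c(1, 1), c(1, 1)), "zero pooled SD")
})

test_that("coupled dyads sit above their shuffle pool almost always", {
  set.seed(303)
  ds <- replicate(60, {
    pool <- sim_pool(4, alpha = 0.8, duration_s = 60)
    pseudo <- pseudosynchrony_distribution(build_surrogate_pool(pool),
                                           sync_params())
    real <- lapply(pool$segments, dyad_synchrony, params = sync_params())
    compare_real_vs_pseudo(real, pseudo)$effect_size_d
  })
  expect_gte(mean(ds > 0), 0.95)
})

test_that("window-size sweep validates parameters and reports one row per size", {
  set.seed(304)
  pool <- sim_pool(4, alpha = 0.6, duration_s = 60)
  sp <- build_surrogate_pool(pool)
  tab <- window_size_sweep(pool, sp, window_list = 10)
  expect_equal(nrow(tab), 1L)
  expect_error(window_size_sweep(pool, sp, window_list = 5), "parameter error")
  tab3 <- window_size_sweep(pool, sp, window_list = c(10, 20, 30))
  expect_equal(tab3$window_s, c(10, 20, 30))
  expect_true(all(tab3$d > 0))           # coupled data: positive ES at all sizes
})

test_that("uncoupled data show near-zero effect size at all window sizes", {
  set.seed(305)
  dsum <- matrix(0, 30, 3)
  for (r in 1:30) {
    pool <- sim_pool(4, alpha = 0, duration_s = 60)
    sp <- build_surrogate_pool(pool)
    dsum[r, ] <- window_size_sweep(pool, sp, window_list = c(10, 20, 30))$d
  }
  expect_true(all(abs(colMeans(dsum)) < 0.3))
})

test_that("the permutation test is reproducible and agrees qualitatively with the effect", {
  set.seed(306)
  pool <- sim_pool(6, alpha = 0.8, duration_s = 60)
  set.seed(1); r1 <- pseudosynchrony_test(pool, sync_params(), n_perm = 500)
  set.seed(1); r2 <- pseudosynchrony_test(pool, sync_params(), n_perm = 500)
  expect_identical(r1$p_value, r2$p_value)
  expect_lt(r1$p_value, 0.05)
  expect_gt(r1$effect_size_d, 0)
  expect_true(is.finite(r1$welch_p))
})
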