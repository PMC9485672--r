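test_that("static scenes yield zero motion energy in every ROI", {
  a <- array(rep(matrix(sample(0:255, 40 * 60, replace = TRUE), 40, 60), 5),
             dim = c(40, 60, 5))
  rois <- list(roi_rect("therapist", "head", 1, 1, 30, 20),
               roi_polygon("patient", "head", c(35, 55, 45), c(5, 5, 25)))
  me <- compute_motion_energy(frame_sequence(a), rois, noise_threshold = 0)
  expect_equal(dim(me$values), c(4L, 2L))
  expect_true(all(me$values == 0))
})

test_that("a translating square matches the per-pixel oracle and the symmetric difference", {
  set.seed(101)
  a <- square_frames(n_frames = 6, size = 10, step = 3)
  r <- roi_rect("patient", "upper_body", 1, 1, 60, 40)
  me <- compute_motion_energy(frame_sequence(a), list(r), noise_threshold = 0)
  # translating a 10-wide square by 3 px changes 2 * 3 * 10 = 60 pixels
  expect_equal(unname(me$values[, 1]), rep(60, 5))
  mask <- rasterize_roi(r, 60, 40)
  expect_equal(unname(me$values[, 1]), oracle_motion_energy(a, mask, 0))
})

test_that("movement outside every ROI is invisible", {
  a <- square_frames(y0 = 25, x0 = 30)                 # blob in lower-right
  rois <- list(roi_rect("therapist", "head", 1, 1, 20, 15))
  me <- compute_motion_energy(frame_sequence(a), rois, noise_threshold = 0)
  expect_true(all(me$values == 0))
})

test_that("random frames agree with the exhaustive per-pixel count", {
  set.seed(102)
  for (thr in c(0, 7, 25)) {
    a <- array(sample(0:255, 20 * 20 * 4, replace = TRUE), dim = c(20, 20, 4))
    rois <- list(roi_rect("therapist", "head", 3, 2, 10, 12),
                 roi_polygon("patient", "head", c(12, 19, 19, 14), c(12, 10, 19, 19)))
    me <- compute_motion_energy(frame_sequence(a), rois, thr)
    for (k in 1:2) {
      mask <- rasterize_roi(rois[[k]], 20, 20)
      expect_equal(unname(me$values[, k]), oracle_motion_energy(a, mask, thr))
    }
  }
})

test_that("energy is invariant under a global illumination offset", {
  set.seed(103)
  a <- array(sample(0:200, 15 * 15 * 3, replace = TRUE), dim = c(15, 15, 3))
  r <- roi_rect("patient", "head", 2, 2, 10, 10)
  m1 <- compute_motion_energy(frame_sequence(a), list(r), 10)
  m2 <- compute_motion_energy(frame_sequence(a + 50), list(r), 10)
  expect_equal(m1$values, m2$values)
})

test_that("lowering the noise threshold never decreases energy, and noise below it is invisible", {
  set.seed(104)
  a <- array(sample(0:255, 20 * 20 * 5, replace = TRUE), dim = c(20, 20, 5))
  r <- roi_rect("patient", "head", 1, 1, 20, 20)
  e <- lapply(c(0, 5, 15, 40), function(thr)
    compute_motion_energy(frame_sequence(a), list(r), thr)$values)
  for (k in 2:4) expect_true(all(e[[k - 1]] >= e[[k]]))
  expect_true(all(e[[1]] <= 400))                     # bounded by ROI area
  # static scene + salt-and-pepper noise of amplitude <= threshold
  base <- matrix(100, 20, 20)
  noisy <- array(base, dim = c(20, 20, 4))
  noisy[, , 2:4] <- noisy[, , 2:4] +
    sample(c(-4, 0, 4), 20 * 20 * 3, replace = TRUE)   # peak-to-peak 8
  me <- compute_motion_energy(frame_sequence(noisy), list(r), noise_threshold = 8)
  expect_true(all(me$values == 0))
})

test_that("combine_rois sums per person and validates labels", {
  vals <- cbind(rep(1, 10), rep(2, 10), rep(3, 10))
  me <- mea_series(vals, labels = c("t.head", "t.upper", "t.lower"))
  comb <- combine_rois(me, list(therapist = c("t.head", "t.upper", "t.lower")))
  expect_equal(unname(comb$values[, 1]), rep(6, 10))
  # single-ROI group is the identity
  one <- combine_rois(me, list(p = "t.head"))
  expect_equal(unname(one$values[, 1]), rep(1, 10))
  # random input vs elementwise-sum oracle
  set.seed(105)
  rv <- matrix(rpois(60, 20), 20, 3)
  rme <- mea_series(rv, labels = c("a", "b", "c"))
  got <- combine_rois(rme, list(p = c("a", "c"), q = "b"))
  expect_equal(unname(got$values[, "p"]), rv[, 1] + rv[, 3])
  expect_error(combine_rois(me, list(p = "nope")), "unknown ROI label")
  expect_error(combine_rois(me, list(p = "t.head", q = "t.head")), "disjoint")
})

test_that("the motion-energy text dialect round-trips exactly and rejects malformed input", {
  set.seed(106)
  vals <- cbind(matrix(rpois(3600 * 5, 30), 3600, 5), runif(3600) * 13.7)
  me <- mea_series(vals, fps = 30)
  f <- tempfile(fileext = ".txt")
  on.exit(unlink(f))
  write_mea_text(me, f)
  back <- read_mea_text(f, fps = 30)
  expect_identical(unname(back$values), unname(vals))

  writeLines(c("1 2 3", "4 5", "6 7 8"), f)
  expect_error(read_mea_text(f), "ragged row 2")
  writeLines(c("1 2", "3 oops"), f)
  expect_error(read_mea_text(f), "row 2, column 2")
  writeLines(c("0 0", "0 0", "0 0"), f)
  z <- read_mea_text(f)
  expect_equal(ncol(z$values), 2L)
  expect_true(all(z$values == 0))
})

test_that("ROIs validate bounds and read from YAML config", {
  expect_error(rasterize_roi(roi_rect("p", "head", 55, 1, 10, 10), 60, 40),
               "bounds error")
  expect_error(compute_motion_energy(frame_sequence(square_frames()),
                                     list(roi_rect("p", "head", 1, 35, 10, 10))),
               "bounds error")
  cfg <- tempfile(fileext = ".yaml")
  on.exit(unlink(cfg))
  writeLines(c(
    "- person: therapist", "  region: head", "  rect: [5, 5, 10, 8]",
    "- person: patient", "  region: head",
    "  polygon: [[20, 5], [30, 5], [25, 15]]"), cfg)
  rois <- read_roi_config(cfg)
  expect_length(rois, 2L)
  expect_equal(rois[[1]]$label, "therapist.head")
  expect_equal(sum(rasterize_roi(rois[[1]], 60, 40)), 80)
  expect_s3_class(rois[[2]], "roi")
  expect_equal(rois[[2]]$shape, "polygon")
})

test_that("mismatched frame sizes and grayscale conversion behave", {
  expect_error(frame_sequence(list(matrix(0, 4, 4), matrix(0, 5, 4))),
               "mismatched")
  rgb <- array(c(100, 50, 200), dim = c(1, 1, 3))
  expect_equal(to_grayscale(rgb)[1, 1], 0.299 * 100 + 0.587 * 50 + 0.114 * 200)
})
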