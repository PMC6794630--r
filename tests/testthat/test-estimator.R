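make_series <- function(times, gel, lumen0 = 600, gel0 = gel[1]) {
  structure(list(times_s = times, gel_mean = gel, I_lumen_0 = lumen0,
                 I_gel_0 = gel0, saturated_fraction = 0),
            class = "bbb_intensity_series")
}

std_cv <- function(vg_over_av_um = 200) {
  control_volume(gel_rows = c(0, 10), gel_cols = c(0, 4),
                 lumen_rows = c(0, 10), lumen_cols = c(6, 10),
                 pixel_size_um = 50, vg_over_av_um = vg_over_av_um)
}

test_that("control volumes validate geometry and compute Vg/Av", {
  cv <- control_volume(gel_rows = c(0, 10), gel_cols = c(0, 4),
                       lumen_rows = c(0, 10), lumen_cols = c(6, 10),
                       pixel_size_um = 50)
  expect_equal(cv$vg_over_av_m, 4 * 50e-6)  # depth of the CV
  expect_equal(cv$Vg_m3 / cv$Av_m2, cv$vg_over_av_m)
  expect_error(control_volume(c(0, 10), c(0, 4), c(0, 10), c(2, 6), 50),
               "disjoint")
  expect_error(control_volume(c(5, 5), c(0, 4), c(0, 10), c(6, 10), 50),
               "half-open")
})

test_that("intensity extraction is exact on synthetic frames", {
  frames <- lapply(0:2, function(k)
    matrix(2 * k, nrow = 10, ncol = 10) + col(matrix(0, 10, 10)))
  tl <- structure(list(frames = frames, timestamps_s = c(0, 300, 600),
                       pixel_size_um = 50, metadata = list(bit_depth = 16)),
                  class = "bbb_timelapse")
  cv <- std_cv()
  s <- extract_intensity_series(tl, cv)
  # mean over cols 1:4 of col index = 2.5, plus the 2k offset
  expect_equal(s$gel_mean, c(2.5, 4.5, 6.5))
  expect_equal(s$I_lumen_0, 8.5)
  expect_equal(s$I_gel_0, 2.5)

  zero <- tl; zero$frames <- lapply(1:3, function(k) matrix(0, 10, 10))
  expect_equal(extract_intensity_series(zero, cv)$gel_mean, c(0, 0, 0))

  bad <- cv; bad$gel_cols <- c(0, 99)
  expect_error(extract_intensity_series(tl, bad), "out of frame")
})

test_that("saturated pixels are excluded and flagged", {
  cap <- 2^16 - 1
  fr <- matrix(100, 10, 10); fr[, 7:8] <- cap     # half the lumen saturated
  fr[1:3, 1:4] <- cap                              # ...and part of the gel
  tl <- structure(list(frames = list(fr, fr, fr),
                       timestamps_s = c(0, 300, 600), pixel_size_um = 50,
                       metadata = list(bit_depth = 16)),
                  class = "bbb_timelapse")
  s <- extract_intensity_series(tl, std_cv())
  expect_equal(s$gel_mean[1], 100)      # saturated rows dropped from mean
  expect_gt(s$saturated_fraction, 0.05)

  fr2 <- matrix(100, 10, 10); fr2[, 7:10] <- cap  # lumen entirely at ceiling
  tl2 <- tl; tl2$frames <- list(fr2, fr2, fr2)
  expect_error(extract_intensity_series(tl2, std_cv()), "saturated")
})

test_that("slope fitting matches exact lines in both modes and errors on thin data", {
  t <- seq(0, 1200, by = 300)
  lin <- make_series(t, 5 + 0.02 * t)
  expect_equal(fit_intensity_slope(lin, "two_point", 600)$slope, 0.02)
  expect_equal(fit_intensity_slope(lin, "regression", 600)$slope, 0.02)
  flat <- make_series(t, rep(7, length(t)))
  expect_equal(fit_intensity_slope(flat, "two_point", 600)$slope, 0)
  expect_error(fit_intensity_slope(lin, "two_point", 450), "needs a frame")
  expect_error(fit_intensity_slope(lin, "regression", 5000), "exceeds")
})

test_that("regression slope is unbiased on noisy lines (Monte Carlo)", {
  t <- seq(0, 600, by = 60)
  true_slope <- 0.05
  set.seed(99)
  est <- replicate(100, {
    s <- make_series(t, 10 + true_slope * t + rnorm(length(t), sd = 1))
    fit_intensity_slope(s, "regression", 600)$slope
  })
  # SE of an OLS slope with unit noise on this design
  se <- 1 / sqrt(sum((t - mean(t))^2))
  expect_lt(abs(mean(est) - true_slope), 3 * se / sqrt(100))
})

test_that("the permeability formula is applied exactly and guards delta_Im", {
  t <- seq(0, 600, by = 300)
  s <- make_series(t, 10 + 0.01 * t, lumen0 = 110, gel0 = 10)  # dIm = 100
  est <- estimate_permeability(s, std_cv(200), "two_point")
  # P = 200 um * 0.01/s / 100 = 2e-8 m/s = 2e-6 cm/s
  expect_equal(est$P_cm_s, 2e-6)
  expect_equal(est$delta_Im, 100)

  flat <- make_series(t, rep(3, 3), lumen0 = 50, gel0 = 3)
  expect_equal(estimate_permeability(flat, std_cv(), "two_point")$P_cm_s, 0)

  dark <- make_series(t, rep(3, 3), lumen0 = 2, gel0 = 3)
  expect_error(estimate_permeability(dark, std_cv()),
               class = "bbb_assay_error")
})

test_that("estimates are invariant to detector gain and offset", {
  tr <- assay_ground_truth(5e-6, layout = short_layout(500), n_frames = 3)
  h <- simulate_dextran_assay(tr, dx_um = 50)
  p <- vapply(list(c(5e4, 0), c(5e4, 250), c(2.3e5, 40)), function(gb) {
    tl <- render_timelapse(h, noiseless_imaging_model(gain = gb[1],
                                                      background = gb[2]))
    estimate_from_timelapse(tl)$P_cm_s
  }, numeric(1))
  expect_lt(diff(range(p)) / mean(p), 0.005)
})

test_that("two-point and regression agree on noiseless assays", {
  e2 <- noiseless_assay_estimate(5e-6, "dextran_40kda", mode = "two_point")
  er <- noiseless_assay_estimate(5e-6, "dextran_40kda", mode = "regression")
  expect_equal(er$P_cm_s / e2$P_cm_s, 1, tolerance = 0.05)
})

test_that("round-trip recovery is accurate in the membrane-limited regime", {
  # when the membrane resistance dominates the gel/lumen diffusion
  # resistance, the two-point read-out recovers the true permeability
  for (P in c(1e-7, 5e-7)) {
    est <- noiseless_assay_estimate(P, "dextran_40kda")
    expect_equal(est$P_cm_s / P, 1, tolerance = 0.03)
  }
})

test_that("back-diffusion biases the read-out progressively low at high permeability", {
  rel_err <- vapply(c(5e-7, 2e-6, 6.45e-6), function(P)
    noiseless_assay_estimate(P, "dextran_40kda")$P_cm_s / P - 1, numeric(1))
  expect_true(all(diff(rel_err) < 0))  # monotone worsening underestimate
  expect_true(all(rel_err <= 0.01))
})
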