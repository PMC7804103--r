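test_that("bias correction: identity on clean input, removes smooth bias", {
  # constant-intensity foreground: nothing to correct (within 1% RMS)
  flat <- volume3d(array(100, c(32, 32, 12)), c(2, 2, 5))
  fg <- array(TRUE, dim(flat$values))
  out <- correct_bias(flat, foreground = fg)
  rms <- sqrt(mean((out$corrected$values - flat$values)^2)) / 100
  expect_lt(rms, 0.01)

  # 20% smooth multiplicative bias: foreground CoV more than halved
  ph <- make_phantom_pair(phantom_spec(bias_amplitude = 0.2))
  wm <- ph$truth$wm_mask
  fg2 <- ph$t1w$values > 200
  corr <- correct_bias(ph$t1w, foreground = fg2)
  cov_of <- function(v) stats::sd(v[wm]) / mean(v[wm])
  expect_lt(cov_of(corr$corrected$values), 0.5 * cov_of(ph$t1w$values))

  # estimated field is smooth: voxel-to-voxel relative steps stay tiny
  lf <- log(corr$field$values)
  steps <- abs(diff(lf[, 16, 6]))
  expect_lt(max(steps), 0.02)

  # nonpositive foreground intensities rejected with advice
  neg <- volume3d(array(c(-1, rep(10, 999)), c(10, 10, 10)))
  expect_error(correct_bias(neg, foreground = array(TRUE, c(10, 10, 10))),
               "shift")
})

test_that("Nyul standardization maps landmarks exactly and is monotone", {
  set.seed(2)
  refs <- list(volume3d(array(rnorm(8000, 100, 20), c(20, 20, 20))),
               volume3d(array(rnorm(8000, 140, 25), c(20, 20, 20))))
  map <- nyul_fit(refs)
  expect_s3_class(map, "intensity_mapping")
  expect_true(all(diff(map$standard_scale) > 0))

  # volume already on the standard scale: identity (landmark-exact, and
  # the piecewise-linear map leaves interior values essentially unchanged)
  map1 <- nyul_fit(refs[1])
  out_id <- nyul_apply(refs[[1]], map1)
  expect_equal(out_id$values, refs[[1]]$values, tolerance = 1e-10)

  # input = standard volume x 2: output landmarks equal the standard scale
  doubled <- volume3d(refs[[1]]$values * 2)
  out <- nyul_apply(doubled, map1)
  lms <- stats::quantile(out$values, map1$percentiles / 100, names = FALSE,
                         type = 7)
  expect_equal(lms, map1$standard_scale, tolerance = 1e-9)

  # monotonicity: intensity order preserved
  x <- as.numeric(doubled$values)
  y <- as.numeric(out$values)
  ord <- order(x)
  expect_true(all(diff(y[ord]) >= -1e-12))

  # degenerate histogram rejected
  expect_error(nyul_apply(volume3d(array(5, c(4, 4, 4))), map1),
               "degenerate")
  expect_error(nyul_fit(list(volume3d(array(1, c(4, 4, 4))))), "degenerate")
})

test_that("resampling preserves extent and reproduces closed forms", {
  set.seed(3)
  vol <- volume3d(array(rnorm(20 * 16 * 8), c(20, 16, 8)), c(1, 1, 5))
  # resample to own spacing: identity
  expect_identical(resample(vol, c(1, 1, 5)), vol)

  # constant stays constant at any spacing
  cvol <- volume3d(array(7, c(12, 12, 6)), c(1, 1, 5))
  rc <- resample(cvol, c(2.5, 3, 2))
  expect_equal(range(rc$values), c(7, 7), tolerance = 1e-12)
  # physical extent preserved within one voxel
  expect_lt(max(abs(dim(rc$values) * rc$spacing_mm -
                    dim(cvol$values) * cvol$spacing_mm)), max(rc$spacing_mm))

  # linear ramp: resampled values equal the ramp at the new voxel centers
  ramp_vals <- array(rep((seq_len(20) - 0.5) * 1, 16 * 8), c(20, 16, 8))
  ramp <- volume3d(ramp_vals, c(1, 1, 1))
  r2 <- resample(ramp, c(2, 2, 2))
  centers <- (seq_len(dim(r2$values)[1]) - 0.5) * 2
  expect_equal(r2$values[, 4, 2], centers, tolerance = 1e-12)

  # nearest-neighbour keeps masks binary
  mv <- volume3d(array(as.numeric(stats::runif(20 * 16 * 8) > 0.5),
                       c(20, 16, 8)), c(1, 1, 5))
  rm2 <- resample(mv, 2, "nearest")
  expect_true(all(rm2$values %in% c(0, 1)))

  expect_error(resample(vol, 0), "positive")
})

test_that("rigid registration recovers identity and known translations", {
  ph <- make_phantom_pair(phantom_spec(grid_shape = c(40, 40, 16),
                                       spacing_mm = c(2, 2, 2),
                                       cavity_radius_mm = 10,
                                       rim_thickness_mm = 4))
  fx <- ph$t1wc
  # moving = fixed: identity within 0.1 mm / 0.1 degree
  tf0 <- register_rigid(fx, fx)
  expect_lt(max(abs(tf0$translation_mm)), 0.1)
  expect_lt(max(abs(tf0$rotation_rad)) * 180 / pi, 0.1)

  # known (2, 3, 0) mm shift recovered within 0.5 mm
  mv <- volume3d(fx$values, fx$spacing_mm, fx$origin_mm + c(2, 3, 0))
  tf <- register_rigid(mv, fx)
  expect_lt(max(abs(tf$translation_mm - c(2, 3, 0))), 0.5)

  # transform composed with its inverse is the identity map
  inv <- invert_rigid(tf)
  pts <- matrix(stats::runif(30, 10, 60), ncol = 3)
  fwd <- resectquant:::rigid_map_points
  roundtrip <- fwd(fwd(pts, tf$rotation_rad, tf$translation_mm,
                       tf$center_mm),
                   inv$rotation_rad, inv$translation_mm, inv$center_mm)
  expect_equal(roundtrip, pts, tolerance = 1e-8)

  # applying the transform aligns the shifted volume with the fixed one
  aligned <- apply_rigid(mv, fx, tf)
  inner <- fx$values[5:36, 5:36, 3:14]
  expect_gt(stats::cor(as.numeric(aligned$values[5:36, 5:36, 3:14]),
                       as.numeric(inner)), 0.999)
})

test_that("intensity matching inverts a known affine distortion", {
  ph <- make_phantom_pair(phantom_spec())
  t1wc <- ph$t1wc
  nonenh <- ph$truth$brain_mask & !ph$truth$rim_mask

  # identical inputs: gain 1, offset 0
  m0 <- match_intensity(t1wc, t1wc, nonenh)
  expect_equal(m0$gain, 1, tolerance = 1e-12)
  expect_equal(m0$offset, 0, tolerance = 1e-9)

  # t1w = 0.5 t1wc + 10 on the mask: recovered map is the inverse affine
  t1w_d <- volume3d(0.5 * t1wc$values + 10, t1wc$spacing_mm)
  mm <- match_intensity(t1w_d, t1wc, nonenh)
  expect_equal(mm$gain, 2, tolerance = 1e-9)
  expect_equal(mm$offset, -20, tolerance = 1e-6)
  # matched mask mean equals target mask mean by construction
  expect_equal(mean(mm$matched$values[nonenh]), mean(t1wc$values[nonenh]),
               tolerance = 1e-9)

  expect_error(match_intensity(volume3d(array(1, dim(t1wc$values)),
                                        t1wc$spacing_mm), t1wc, nonenh),
               "variance")
})

test_that("subtraction contract and the noise-free phantom oracle", {
  ph <- make_phantom_pair(phantom_spec())
  z <- subtract(ph$t1wc, ph$t1wc)
  expect_true(all(z$values == 0))

  s <- subtract(ph$t1wc, ph$t1w)
  expect_identical(s$values > 0, ph$truth$rim_mask)
  expect_true(all(s$values[ph$truth$rim_mask] ==
                  phantom_spec()$rim_enhancement))

  # anti-symmetry
  expect_equal(subtract(ph$t1w, ph$t1wc)$values, -s$values)

  # grid mismatch rejected
  other <- volume3d(array(0, c(4, 4, 4)))
  expect_error(subtract(ph$t1wc, other), "grid")
})

test_that("full preprocessing of a clean phantom recovers the exact rim", {
  ph <- make_phantom_pair(phantom_spec())
  nonenh <- ph$t1wc$values > mean(ph$t1wc$values) & !ph$truth$rim_mask
  matched <- match_intensity(ph$t1w, ph$t1wc, nonenh)$matched
  sub_map <- subtract(ph$t1wc, matched)
  m <- segment_enhancement(sub_map, phantom_spec()$rim_enhancement / 2)
  expect_identical(m$mask, ph$truth$rim_mask)
  # metadata preserved through every stage
  expect_equal(sub_map$spacing_mm, ph$t1wc$spacing_mm)
  expect_equal(sub_map$origin_mm, ph$t1wc$origin_mm)
})
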