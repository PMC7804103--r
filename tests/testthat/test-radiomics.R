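native_cfg <- radiomics_config(resample_spacing_mm = NULL, bin_width = 10)

test_that("feature vector has the contracted size and family counts", {
  set.seed(11)
  img <- volume3d(array(stats::runif(16^3, 0, 100), c(16, 16, 16)))
  m <- array(FALSE, c(16, 16, 16)); m[5:12, 4:11, 6:13] <- TRUE
  fv <- extract_features(img, enhancement_mask(m, c(1, 1, 1)), native_cfg)
  expect_length(fv, 94)
  expect_true(all(is.finite(fv)))
  counts <- table(attr(fv, "family"))
  expect_equal(as.integer(counts[c("firstorder", "glcm", "glrlm", "glszm",
                                   "ngtdm", "gldm")]),
               c(19L, 24L, 16L, 16L, 5L, 14L))
  expect_false(any(duplicated(names(fv))))
})

test_that("first-order features match direct formulas on a known sample", {
  vals <- c(10, 10, 20, 30, 30, 30, 40, 55)
  img <- volume3d(array(rep(vals, length.out = 27), c(3, 3, 3)))
  m <- array(FALSE, c(3, 3, 3)); m[1:2, 1:2, 1:2] <- TRUE
  img$values[m] <- vals
  fv <- extract_features(img, enhancement_mask(m, c(1, 1, 1)), native_cfg)
  expect_equal(unname(fv["firstorder_Mean"]), mean(vals))
  expect_equal(unname(fv["firstorder_Energy"]), sum(vals^2))
  expect_equal(unname(fv["firstorder_Median"]), stats::median(vals))
  expect_equal(unname(fv["firstorder_Range"]), 45)
  expect_equal(unname(fv["firstorder_Variance"]),
               mean((vals - mean(vals))^2))
  expect_equal(unname(fv["firstorder_RootMeanSquared"]),
               sqrt(mean(vals^2)))
  # discretized histogram entropy: levels floor((v-10)/10)+1
  lev <- floor((vals - 10) / 10) + 1
  p <- as.numeric(table(lev)) / length(lev)
  expect_equal(unname(fv["firstorder_Entropy"]), -sum(p * log2(p)),
               tolerance = 1e-9)
  expect_equal(unname(fv["firstorder_Uniformity"]), sum(p^2),
               tolerance = 1e-12)
})

test_that("GLCM features agree with a brute-force matrix on a tiny case", {
  set.seed(12)
  img <- volume3d(array(sample(0:49, 4^3, replace = TRUE), c(4, 4, 4)))
  m <- array(TRUE, c(4, 4, 4))
  fv <- extract_features(img, enhancement_mask(m, c(1, 1, 1)), native_cfg)

  disc <- resectquant:::discretize_mask(img$values, m, native_cfg)
  ng <- max(disc, na.rm = TRUE)
  offs <- resectquant:::unique_offsets_13()
  # independent route: brute-force pair loops + direct feature formulas
  contrast <- energy <- maxp <- autoc <- 0
  for (r in seq_len(nrow(offs))) {
    P <- brute_glcm(disc, offs[r, ], ng)
    ii <- row(P); jj <- col(P)
    contrast <- contrast + sum((ii - jj)^2 * P)
    energy <- energy + sum(P^2)
    maxp <- maxp + max(P)
    autoc <- autoc + sum(ii * jj * P)
  }
  n_off <- nrow(offs)
  expect_equal(unname(fv["glcm_Contrast"]), contrast / n_off,
               tolerance = 1e-12)
  expect_equal(unname(fv["glcm_JointEnergy"]), energy / n_off,
               tolerance = 1e-12)
  expect_equal(unname(fv["glcm_MaximumProbability"]), maxp / n_off,
               tolerance = 1e-12)
  expect_equal(unname(fv["glcm_Autocorrelation"]), autoc / n_off,
               tolerance = 1e-12)
})

test_that("GLRLM run counts match a brute-force walker", {
  set.seed(13)
  img <- volume3d(array(sample(c(5, 15, 25), 5^3, replace = TRUE),
                        c(5, 5, 5)))
  m <- array(stats::runif(5^3) > 0.2, c(5, 5, 5))
  disc <- resectquant:::discretize_mask(img$values, m, native_cfg)
  offs <- resectquant:::unique_offsets_13()
  for (r in c(1, 5, 9, 13)) {
    fast <- resectquant:::glrlm_runs(disc, offs[r, ])
    slow <- brute_glrlm_runs(disc, offs[r, ])
    expect_equal(table(fast[, 1], fast[, 2]), table(slow[, 1], slow[, 2]))
  }
})

test_that("degenerate constant region yields zero-texture features", {
  img <- volume3d(array(50, c(8, 8, 8)))
  m <- array(FALSE, c(8, 8, 8)); m[3:6, 3:6, 3:6] <- TRUE
  fv <- extract_features(img, enhancement_mask(m, c(1, 1, 1)), native_cfg)
  expect_equal(unname(fv["firstorder_Variance"]), 0)
  expect_equal(unname(fv["glcm_JointEntropy"]), 0, tolerance = 1e-9)
  # single gray level: every run spans the whole line; GLRLM gray-level
  # non-uniformity equals the run count
  expect_equal(unname(fv["glszm_GrayLevelNonUniformity"]), 1)
  expect_true(all(is.finite(fv)))
})

test_that("translation invariance and bin-width shift behaviour", {
  set.seed(14)
  img <- volume3d(array(stats::runif(12^3, 0, 80), c(12, 12, 12)))
  m <- array(FALSE, c(12, 12, 12)); m[4:9, 3:8, 5:10] <- TRUE
  fv <- extract_features(img, enhancement_mask(m, c(1, 1, 1)), native_cfg)

  img_t <- volume3d(array(0, c(12, 12, 12)))
  img_t$values[2:12, 2:12, 2:12] <- img$values[1:11, 1:11, 1:11]
  m_t <- array(FALSE, c(12, 12, 12)); m_t[5:10, 4:9, 6:11] <- TRUE
  fv_t <- extract_features(img_t, enhancement_mask(m_t, c(1, 1, 1)),
                           native_cfg)
  expect_equal(fv_t, fv, tolerance = 1e-12)

  # shifting intensities by a bin-width multiple: texture unchanged,
  # first-order mean shifts by the constant
  img_s <- volume3d(img$values + 20)
  fv_s <- extract_features(img_s, enhancement_mask(m, c(1, 1, 1)),
                           native_cfg)
  tex <- !grepl("^firstorder", names(fv))
  expect_equal(fv_s[tex], fv[tex], tolerance = 1e-12)
  expect_equal(unname(fv_s["firstorder_Mean"] - fv["firstorder_Mean"]), 20)
})

test_that("robustness screen: CoV definition and flags", {
  set.seed(15)
  ph <- make_phantom_pair(phantom_spec(noise_sd = 5, seed = 2))
  sub_map <- subtract(ph$t1wc, ph$t1w)
  m <- segment_enhancement(sub_map, 150)

  # identical settings twice: CoV 0 everywhere, all robust
  rb0 <- robustness_screen(ph$t1wc, m,
                           perturbations = list(c(1, 10), c(1, 10)))
  expect_equal(nrow(rb0), 94)
  expect_true(all(rb0$cov_percent[!rb0$zero_mean] == 0))
  expect_true(all(rb0$robust[!rb0$zero_mean]))

  # spacing perturbation: voxel-count-proportional features are fragile
  rb <- robustness_screen(ph$t1wc, m,
                          perturbations = list(c(1, 10), c(2, 10)))
  # Energy scales with voxel count under resampling: high CoV expected
  e_cov <- rb$cov_percent[rb$feature == "firstorder_Energy"]
  mean_cov <- rb$cov_percent[rb$feature == "firstorder_Mean"]
  expect_gt(e_cov, 20)
  expect_lt(mean_cov, e_cov)
  expect_true(all(rb$robust %in% c(TRUE, FALSE)))
  expect_setequal(rb$feature, rb0$feature)

  expect_error(robustness_screen(ph$t1wc, m,
                                 perturbations = list(c(1, 10))),
               "two perturbations")
})

test_that("mask vanishing under resampling gives the sentinel", {
  img <- volume3d(array(stats::runif(6^3), c(6, 6, 6)), c(0.5, 0.5, 0.5))
  m <- array(FALSE, c(6, 6, 6)); m[3, 3, 3] <- TRUE
  out <- extract_features(img, enhancement_mask(m, c(0.5, 0.5, 0.5)),
                          radiomics_config(resample_spacing_mm = 3))
  expect_null(out)
})
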