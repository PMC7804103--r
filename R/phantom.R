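#' Specification of a synthetic post-operative brain phantom
#'
#' Describes a resection cavity with an enhancing rim inside a simplified
#' brain, on an anisotropic grid (default 1 x 1 x 5 mm, matching typical
#' 5 mm-slice post-operative T1 acquisitions). The rim is a closed spherical
#' shell: a voxel belongs to the rim iff the distance of its center to
#' `cavity_center_mm` lies in `[cavity_radius_mm, cavity_radius_mm +
#' rim_thickness_mm)`. The contrast volume equals the pre-contrast volume
#' plus `rim_enhancement` on the rim, before bias and noise are applied.
#'
#' @param grid_shape integer length-3, voxels per axis.
#' @param spacing_mm voxel size per axis (mm).
#' @param cavity_center_mm physical center of the resection cavity (mm);
#'   default is the grid center.
#' @param cavity_radius_mm cavity radius (mm).
#' @param rim_thickness_mm thickness of the enhancing rim (mm); 0 = no rim.
#' @param rim_enhancement intensity added to the rim on the post-contrast
#'   volume.
#' @param tissue_intensities named list with `background`, `white_matter`,
#'   `gray_matter`, `cavity` baseline intensities.
#' @param bias_amplitude relative amplitude of the smooth multiplicative
#'   bias field (0 = none).
#' @param noise_sd additive Gaussian noise standard deviation.
#' @param seed integer seed; same seed reproduces the phantom bit-for-bit.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(64, 64, 24),
                         spacing_mm = c(1, 1, 5),
                         cavity_center_mm = NULL,
                         cavity_radius_mm = 12,
                         rim_thickness_mm = 4,
                         rim_enhancement = 300,
                         tissue_intensities = list(background = 50,
                                                   white_matter = 400,
                                                   gray_matter = 550,
                                                   cavity = 150),
                         bias_amplitude = 0,
                         noise_sd = 0,
                         seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  spacing_mm <- as.numeric(spacing_mm)
  extent <- grid_shape * spacing_mm
  if (is.null(cavity_center_mm)) cavity_center_mm <- extent / 2
  if (any(spacing_mm <= 0)) stop("spacing must be strictly positive")
  if (rim_thickness_mm < 0) stop("rim_thickness_mm must be >= 0")
  if (cavity_radius_mm <= 0) stop("cavity_radius_mm must be > 0")
  outer <- cavity_radius_mm + rim_thickness_mm
  if (any(cavity_center_mm - outer < 0) ||
      any(cavity_center_mm + outer > extent))
    stop("cavity (including rim) does not fit inside the grid",
         call. = FALSE)
  structure(list(grid_shape = grid_shape, spacing_mm = spacing_mm,
                 cavity_center_mm = as.numeric(cavity_center_mm),
                 cavity_radius_mm = cavity_radius_mm,
                 rim_thickness_mm = rim_thickness_mm,
                 rim_enhancement = rim_enhancement,
                 tissue_intensities = tissue_intensities,
                 bias_amplitude = bias_amplitude,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "phantom_spec")
}

# distance of every voxel center to a physical point, on the spec's grid
voxel_center_distance <- function(grid_shape, spacing_mm, center_mm) {
  xs <- (seq_len(grid_shape[1]) - 0.5) * spacing_mm[1]
  ys <- (seq_len(grid_shape[2]) - 0.5) * spacing_mm[2]
  zs <- (seq_len(grid_shape[3]) - 0.5) * spacing_mm[3]
  dx2 <- (xs - center_mm[1])^2
  dy2 <- (ys - center_mm[2])^2
  dz2 <- (zs - center_mm[3])^2
  sqrt(outer(outer(dx2, dy2, `+`), dz2, `+`))
}

#' Generate a synthetic T1w / T1wC phantom pair with ground truth
#'
#' Builds a simplified brain (white-matter ball with a gray-matter shell),
#' carves a resection cavity, and adds an enhancing rim of known thickness
#' to the post-contrast volume. Identical smooth multiplicative bias is
#' applied to both volumes (coil-dependent), then independent Gaussian
#' noise.
#'
#' @param spec a [phantom_spec].
#' @return list with elements `t1w`, `t1wc` ([volume3d]) and `truth`
#'   (list with `rim_mask` logical array, `rim_thickness_mm`,
#'   `cavity_radius_mm`, `brain_mask`, `wm_mask`).
#' @export
make_phantom_pair <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- voxel_center_distance(spec$grid_shape, spec$spacing_mm,
                             spec$cavity_center_mm)
  ti <- spec$tissue_intensities
  extent <- spec$grid_shape * spec$spacing_mm
  brain_center <- extent / 2
  db <- voxel_center_distance(spec$grid_shape, spec$spacing_mm, brain_center)
  brain_r <- min(extent) / 2 * 0.9
  brain <- db <= brain_r
  gm <- db > brain_r * 0.82 & brain
  t1w <- array(ti$background, spec$grid_shape)
  t1w[brain] <- ti$white_matter
  t1w[gm] <- ti$gray_matter
  cavity <- d < spec$cavity_radius_mm
  t1w[cavity] <- ti$cavity
  rim <- d >= spec$cavity_radius_mm &
         d < spec$cavity_radius_mm + spec$rim_thickness_mm
  t1wc <- t1w
  t1wc[rim] <- t1wc[rim] + spec$rim_enhancement

  vol_w <- volume3d(t1w, spec$spacing_mm)
  vol_c <- volume3d(t1wc, spec$spacing_mm)
  if (spec$bias_amplitude > 0) {
    bias <- bias_field(spec$grid_shape, spec$spacing_mm, spec$bias_amplitude)
    vol_w$values <- vol_w$values * bias
    vol_c$values <- vol_c$values * bias
  }
  if (spec$noise_sd > 0) {
    rng <- local_rng(spec$seed)
    vol_w$values <- vol_w$values +
      array(rng$rnorm(prod(spec$grid_shape), sd = spec$noise_sd),
            spec$grid_shape)
    vol_c$values <- vol_c$values +
      array(rng$rnorm(prod(spec$grid_shape), sd = spec$noise_sd),
            spec$grid_shape)
  }
  truth <- list(rim_mask = rim, rim_thickness_mm = spec$rim_thickness_mm,
                cavity_radius_mm = spec$cavity_radius_mm,
                brain_mask = brain, wm_mask = brain & !gm & !cavity & !rim)
  list(t1w = vol_w, t1wc = vol_c, truth = truth)
}

# smooth multiplicative field in [1 - A, 1 + A]: single low-frequency cosine
# mode per axis (period = twice the field of view), so all spectral energy
# sits at the lowest nonzero frequency
bias_field <- function(grid_shape, spacing_mm, amplitude) {
  xs <- cos(pi * (seq_len(grid_shape[1]) - 0.5) / grid_shape[1])
  ys <- cos(pi * (seq_len(grid_shape[2]) - 0.5) / grid_shape[2])
  zs <- cos(pi * (seq_len(grid_shape[3]) - 0.5) / grid_shape[3])
  f <- outer(outer(xs, ys, `+`), zs, `+`) / 3
  1 + amplitude * f
}

# Seed-scoped RNG: draws do not disturb (or depend on) the caller's RNG state.
local_rng <- function(seed) {
  state <- NULL
  with_state <- function(f) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                        globalenv()) else NULL
    if (is.null(state)) set.seed(seed) else assign(".Random.seed", state,
                                                   globalenv())
    on.exit({
      state <<- get(".Random.seed", globalenv())
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, globalenv())
    })
    f()
  }
  list(
    rnorm = function(n, mean = 0, sd = 1)
      with_state(function() stats::rnorm(n, mean, sd)),
    runif = function(n, min = 0, max = 1)
      with_state(function() stats::runif(n, min, max)),
    rexp = function(n, rate = 1) with_state(function() stats::rexp(n, rate)),
    rbinom = function(n, size, prob)
      with_state(function() stats::rbinom(n, size, prob)),
    sample = function(x, size, replace = FALSE, prob = NULL)
      with_state(function() sample(x, size, replace, prob))
  )
}

#' Specification of a synthetic DSC signal-time curve
#'
#' The bolus is a gamma-variate dip in the T2*-weighted signal. Contrast
#' leakage is injected in the relaxation-rate domain exactly as the
#' Boxerman-Schmainda-Weiskoff correction models it: the voxel's
#' delta-R2* curve is the leak-free bolus minus `k2_leak` times the running
#' integral of the bolus, so the correction can be tested for exact
#' recovery. Positive `k2_leak` therefore produces the T1-dominant leakage
#' signature seen without contrast preload: the post-bolus signal drifts
#' above the leak-free plateau (percentage signal recovery can exceed 100%).
#'
#' @param n_timepoints number of dynamic acquisitions.
#' @param n_baseline pre-bolus baseline points (default 10).
#' @param s0 baseline signal level.
#' @param bolus_depth fractional signal drop at the nadir, in `[0, 1)`.
#' @param bolus_t0 bolus arrival (sample index units).
#' @param bolus_width gamma-variate scale (sample index units).
#' @param k2_leak leakage rate (per sample; 0 = no leakage).
#' @param recovery_level leak-free post-bolus plateau as fraction of `s0`.
#' @param noise_sd additive Gaussian noise s.d. on the signal.
#' @param te_ms echo time in milliseconds.
#' @param seed integer seed.
#' @return an object of class `dsc_curve_spec`.
#' @export
dsc_curve_spec <- function(n_timepoints = 60, n_baseline = 10, s0 = 1000,
                           bolus_depth = 0.4, bolus_t0 = 12, bolus_width = 3,
                           k2_leak = 0, recovery_level = 0.9, noise_sd = 0,
                           te_ms = 40, seed = 1L) {
  if (n_baseline <= 0 || n_baseline >= n_timepoints)
    stop("need 0 < n_baseline < n_timepoints", call. = FALSE)
  if (bolus_depth < 0 || bolus_depth >= 1)
    stop("need 0 <= bolus_depth < 1", call. = FALSE)
  if (s0 <= 0 || te_ms <= 0) stop("s0 and te_ms must be positive")
  if (recovery_level <= 0) stop("recovery_level must be positive")
  structure(as.list(environment()), class = "dsc_curve_spec")
}

# gamma-variate kernel: zero before onset t0, unit peak at t0 + width
gamma_variate <- function(t, t0, width, alpha = 3) {
  u <- (t - t0) / width
  ifelse(u > 0, u^alpha * exp(alpha * (1 - u)), 0)
}

#' Generate one synthetic DSC curve
#'
#' @param spec a [dsc_curve_spec].
#' @return a `perfusion_curve`: list with `signal`, `n_baseline`, `te_ms`,
#'   and the noise-free components (`signal_clean`, `delta_r2s_true`) for
#'   recovery tests.
#' @export
make_dsc_curve <- function(spec) {
  stopifnot(inherits(spec, "dsc_curve_spec"))
  t <- seq_len(spec$n_timepoints)
  g <- gamma_variate(t, spec$bolus_t0, spec$bolus_width)
  te_s <- spec$te_ms / 1000
  amp <- -log(1 - spec$bolus_depth) / te_s        # peak delta-R2* (1/s)
  cum <- cumsum(g)
  plateau <- -log(spec$recovery_level) / te_s     # persistent rate elevation
  cnorm <- if (max(cum) > 0) cum / max(cum) else cum
  dr2_clean <- amp * g + plateau * cnorm          # leak-free delta-R2*
  dr2 <- dr2_clean - spec$k2_leak * amp * cum     # Boxerman leakage term
  signal_clean <- spec$s0 * exp(-te_s * dr2_clean)
  signal <- spec$s0 * exp(-te_s * dr2)
  if (spec$noise_sd > 0) {
    rng <- local_rng(spec$seed)
    signal <- signal + rng$rnorm(length(signal), sd = spec$noise_sd)
  }
  structure(list(signal = signal, n_baseline = spec$n_baseline,
                 te_ms = spec$te_ms, signal_clean = signal_clean,
                 delta_r2s_true = dr2_clean, spec = spec),
            class = "perfusion_curve")
}

#' Specification of a synthetic survival cohort
#'
#' Survival times follow an exponential hazard
#' `baseline_hazard * exp(log_hr_per_mm * w_g * thickness)` where `w_g` is a
#' per-scan-delay-window multiplier (all 1 by default). Censoring is an
#' independent exponential time whose rate is calibrated numerically so the
#' expected censored fraction equals `censor_rate` (non-informative, so Cox
#' estimates are unbiased).
#'
#' @param n_patients cohort size.
#' @param log_hr_per_mm true log hazard ratio per mm of mean rim thickness.
#' @param baseline_hazard exponential event rate per day at zero thickness.
#' @param censor_rate target expected fraction of censored records.
#' @param thickness_mean,thickness_sd mean rim thickness distribution (mm);
#'   draws are truncated at 0.1 mm.
#' @param scan_delay_probs probabilities of the four surgery-to-scan windows
#'   `<24 h, 24-<48 h, 48-<72 h, >=72 h` (default: the window frequencies of
#'   a typical early post-operative series).
#' @param window_hr_multipliers length-4 multipliers applied to
#'   `log_hr_per_mm` per window (used to emulate a thickness-survival
#'   association restricted to some windows).
#' @param age_mean,age_sd age distribution (years), truncated to `[18, 90]`.
#' @param kps_high_prob probability of post-operative KPS >= 90.
#' @param seed integer seed.
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 144, log_hr_per_mm = log(2),
                        baseline_hazard = 2e-4, censor_rate = 0.2,
                        thickness_mean = 3, thickness_sd = 1.5,
                        scan_delay_probs = c(26, 51, 42, 25) / 144,
                        window_hr_multipliers = c(1, 1, 1, 1),
                        age_mean = 59, age_sd = 12, kps_high_prob = 0.5,
                        seed = 1L) {
  if (n_patients < 2) stop("n_patients must be >= 2", call. = FALSE)
  if (abs(sum(scan_delay_probs) - 1) > 1e-8)
    stop("scan_delay_probs must sum to 1", call. = FALSE)
  if (censor_rate < 0 || censor_rate >= 1)
    stop("censor_rate must be in [0, 1)", call. = FALSE)
  structure(as.list(environment()), class = "cohort_spec")
}

scan_delay_levels <- c("lt24", "24to48", "48to72", "ge72")

#' Generate a synthetic patient cohort with known hazard structure
#'
#' @param spec a [cohort_spec].
#' @return list with `records` (data.frame, one row per patient: `id`,
#'   `os_days`, `os_event`, `pfs_days`, `pfs_event`, `age_years`, `kps_high`,
#'   `scan_delay_group`, `mean_thickness_mm`, `measurable`) and `truth`
#'   (generator parameters plus per-patient hazards).
#' @export
make_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_patients
  rng <- local_rng(spec$seed)
  thick <- pmax(rng$rnorm(n, spec$thickness_mean, spec$thickness_sd), 0.1)
  grp <- factor(scan_delay_levels[
    rng$sample(1:4, n, replace = TRUE, prob = spec$scan_delay_probs)],
    levels = scan_delay_levels)
  wmult <- spec$window_hr_multipliers[as.integer(grp)]
  lambda <- spec$baseline_hazard * exp(spec$log_hr_per_mm * wmult * thick)
  t_event <- rng$rexp(n, rate = 1) / lambda
  if (spec$censor_rate > 0) {
    # calibrate censoring rate c: mean over patients of c/(c+lambda) = target
    f <- function(cc) mean(cc / (cc + lambda)) - spec$censor_rate
    cc <- stats::uniroot(f, c(1e-12, 1e3), tol = 1e-12)$root
    t_cens <- rng$rexp(n, rate = 1) / cc
  } else {
    t_cens <- rep(Inf, n)
  }
  os_days <- pmin(t_event, t_cens)
  os_event <- as.integer(t_event <= t_cens)
  # progression precedes death: PFS hazard higher by a fixed factor
  t_prog <- rng$rexp(n, rate = 1) / (1.5 * lambda)
  pfs_days <- pmin(t_prog, t_event, t_cens)
  pfs_event <- as.integer(pmin(t_prog, t_event) <= t_cens)
  age <- pmin(pmax(rng$rnorm(n, spec$age_mean, spec$age_sd), 18), 90)
  kps_high <- rng$rbinom(n, 1, spec$kps_high_prob)
  records <- data.frame(
    id = sprintf("P%04d", seq_len(n)),
    os_days = os_days, os_event = os_event,
    pfs_days = pfs_days, pfs_event = pfs_event,
    age_years = age, kps_high = kps_high,
    scan_delay_group = grp,
    mean_thickness_mm = thick,
    measurable = TRUE,
    stringsAsFactors = FALSE)
  truth <- list(log_hr_per_mm = spec$log_hr_per_mm,
                window_hr_multipliers = spec$window_hr_multipliers,
                baseline_hazard = spec$baseline_hazard,
                hazard = lambda, thickness = thick)
  list(records = records, truth = truth)
}
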