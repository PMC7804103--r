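#' Construct a perfusion curve
#'
#' @param signal numeric signal-time vector.
#' @param n_baseline number of pre-bolus baseline samples.
#' @param te_ms echo time (ms).
#' @export
perfusion_curve <- function(signal, n_baseline = 10, te_ms = 40) {
  signal <- as.numeric(signal)
  if (n_baseline <= 0 || n_baseline >= length(signal))
    stop("need 0 < n_baseline < length(signal)", call. = FALSE)
  if (!all(is.finite(signal))) stop("signal must be finite", call. = FALSE)
  structure(list(signal = signal, n_baseline = n_baseline, te_ms = te_ms),
            class = "perfusion_curve")
}

curve_signal <- function(curve) {
  if (inherits(curve, "perfusion_curve")) curve$signal else as.numeric(curve)
}

#' Select bolus-bearing curves by Gaussian resemblance
#'
#' Each curve is low-pass filtered (moving average), min-max normalized to
#' `[-1, 0]` so the bolus dip maps to -1, and a Gaussian-shaped dip is
#' least-squares fitted (center/width grid plus refinement). The curve is
#' kept iff the Pearson correlation between the normalized curve and the
#' fitted Gaussian reaches `gaussian_r_min`. Original, unfiltered signal
#' values are retained for kept curves; constant curves are rejected
#' (normalization undefined).
#'
#' @param curves list of `perfusion_curve` (or numeric vectors).
#' @param smoothing moving-average window width (samples).
#' @param gaussian_r_min minimum correlation with the fitted Gaussian dip.
#' @return list with `kept` (list of original curves), `rejected`,
#'   `kept_idx`, `rejected_idx`, `r` (correlation per curve).
#' @export
filter_curves <- function(curves, smoothing = 3, gaussian_r_min = 0.9) {
  if (length(curves) < 1) stop("need at least one curve", call. = FALSE)
  r <- vapply(curves, function(cv) {
    s <- curve_signal(cv)
    sf <- moving_average(s, smoothing)
    if (max(sf) == min(sf)) return(NA_real_)   # constant: rejected
    norm <- (sf - max(sf)) / (max(sf) - min(sf))  # in [-1, 0], dip at -1
    gaussian_dip_fit(norm)
  }, numeric(1))
  keep <- !is.na(r) & r >= gaussian_r_min
  list(kept = curves[keep], rejected = curves[!keep],
       kept_idx = which(keep), rejected_idx = which(!keep), r = r)
}

moving_average <- function(x, w) {
  if (w <= 1) return(x)
  n <- length(x)
  k <- rep(1 / w, w)
  # centered moving average with edge truncation
  pad <- (w - 1) %/% 2
  xe <- c(rep(x[1], pad), x, rep(x[n], w - 1 - pad))
  as.numeric(stats::filter(xe, k, sides = 1))[(w):(n + w - 1)]
}

# best correlation between the normalized curve and a least-squares-fitted
# Gaussian dip. The model is a Gaussian dip plus its own cumulative (a
# recovery step), because physiological curves plateau below baseline after
# the bolus; amplitudes are solved by OLS, center/width by a coarse grid
# plus Nelder-Mead. Returns the Pearson correlation between the normalized
# curve and the fitted model.
gaussian_dip_fit <- function(norm) {
  n <- length(norm)
  t <- seq_len(n)
  score <- function(par) {
    if (any(!is.finite(par))) return(1)
    sig <- max(par[2], 0.5)
    g <- -exp(-0.5 * ((t - par[1]) / sig)^2)
    step <- cumsum(g) / max(-cumsum(g)[n], 1)    # normalized recovery step
    X <- cbind(1, g, step)
    fit <- stats::lm.fit(X, norm)
    pred <- norm - fit$residuals
    sdp <- stats::sd(pred)
    if (!is.finite(sdp) || sdp == 0) return(1)
    cc <- stats::cor(norm, pred)
    if (is.finite(cc)) -cc else 1
  }
  mu0 <- which.min(norm)
  best <- c(mu0, 2); bestv <- score(best)
  for (mu in unique(pmax(2, pmin(n - 1, mu0 + (-2:2)))))
    for (sig in c(1, 2, 3, 5, 8, 12)) {
      v <- score(c(mu, sig))
      if (v < bestv) { bestv <- v; best <- c(mu, sig) }
    }
  o <- stats::optim(best, score, method = "Nelder-Mead",
                    control = list(maxit = 200, reltol = 1e-8))
  -min(o$value, bestv)
}

#' Convert a signal curve to delta-R2*
#'
#' `deltaR2*(t) = -(1/TE) * log(S(t) / S0)` with `S0` the mean of the
#' pre-bolus baseline samples. TE is taken in seconds, so the result is in
#' 1/s.
#'
#' @param curve a `perfusion_curve` (all samples strictly positive).
#' @param te_ms echo time (ms); defaults to the curve's.
#' @return numeric delta-R2* series (1/s).
#' @export
delta_r2star <- function(curve, te_ms = NULL) {
  stopifnot(inherits(curve, "perfusion_curve"))
  if (is.null(te_ms)) te_ms <- curve$te_ms
  s <- curve$signal
  if (any(s <= 0))
    stop("nonpositive signal sample(s) at index ",
         paste(utils::head(which(s <= 0), 3), collapse = ", "),
         "; cannot take log", call. = FALSE)
  s0 <- mean(s[seq_len(curve$n_baseline)])
  if (s0 <= 0) stop("nonpositive baseline mean", call. = FALSE)
  -(1000 / te_ms) * log(s / s0)
}

#' Boxerman-Schmainda-Weiskoff leakage correction
#'
#' Each voxel's delta-R2* curve is regressed on a non-enhancing reference
#' curve and its running time integral:
#' `dR2*(t) ~ K1 * ref(t) - K2 * int_0^t ref`. The corrected curve adds the
#' leakage term back: `dR2*(t) + K2 * int_0^t ref`. `K2 > 0` corresponds to
#' T1-dominant leakage (post-bolus signal above baseline), the expected
#' regime for gradient-echo acquisitions without contrast preload.
#'
#' @param dr2_curves numeric matrix, one row per voxel, columns = time.
#' @param reference_curve mean delta-R2* over non-enhancing kept voxels.
#' @param dt time step between samples (s); the integral uses cumulative
#'   trapezoids times `dt`.
#' @return list with `corrected` (matrix), `k1`, `k2` (per-voxel vectors).
#' @export
boxerman_correct <- function(dr2_curves, reference_curve, dt = 1) {
  if (is.null(dim(dr2_curves))) dr2_curves <- matrix(dr2_curves, nrow = 1)
  ref <- as.numeric(reference_curve)
  if (all(ref == 0)) stop("degenerate (all-zero) reference curve",
                          call. = FALSE)
  if (ncol(dr2_curves) != length(ref))
    stop("curve length mismatch with reference", call. = FALSE)
  cref <- cumtrapz(ref, dt)
  X <- cbind(ref, -cref)
  XtX <- crossprod(X)
  coefs <- t(solve(XtX, crossprod(X, t(dr2_curves))))
  k1 <- coefs[, 1]
  k2 <- coefs[, 2]
  corrected <- dr2_curves + outer(k2, cref)
  list(corrected = corrected, k1 = as.numeric(k1), k2 = as.numeric(k2))
}

# cumulative trapezoidal integral with step dt, starting at 0
cumtrapz <- function(x, dt = 1) {
  n <- length(x)
  c(0, cumsum((x[-1] + x[-n]) / 2)) * dt
}

# bolus integration window from the reference curve: from the end of the
# baseline to the point after the peak where the curve first falls below 10%
# of the peak (or the start of the final quarter, whichever is earlier)
bolus_window <- function(ref, n_baseline) {
  n <- length(ref)
  peak <- which.max(ref)
  tail_start <- n - floor(n / 4) + 1
  post <- which(ref[peak:n] < 0.1 * ref[peak])
  end <- if (length(post)) peak + post[1] - 1 else tail_start
  c(n_baseline + 1, min(max(end, peak + 1), n))
}

#' Relative cerebral blood volume map, white-matter normalized
#'
#' Per voxel, the trapezoidal integral of the corrected delta-R2* over the
#' bolus window (detected from the reference curve), divided by the mean
#' integral over the contralateral white-matter ROI; the WM mean of the
#' output is 1 by construction.
#'
#' @param corrected matrix of leakage-corrected delta-R2* (rows = voxels).
#' @param wm_rows indices of rows belonging to the white-matter ROI.
#' @param reference_curve the reference delta-R2* used to detect the bolus
#'   window; defaults to the WM mean curve.
#' @param n_baseline baseline length (samples).
#' @param dt time step (s).
#' @return list with `rcbv` (per-row values), `window` (sample index range),
#'   `wm_integral`.
#' @export
rcbv_map <- function(corrected, wm_rows, reference_curve = NULL,
                     n_baseline = 10, dt = 1) {
  if (is.null(dim(corrected))) corrected <- matrix(corrected, nrow = 1)
  if (length(wm_rows) < 1) stop("white-matter ROI is empty", call. = FALSE)
  if (is.null(reference_curve))
    reference_curve <- colMeans(corrected[wm_rows, , drop = FALSE])
  win <- bolus_window(reference_curve, n_baseline)
  idx <- win[1]:win[2]
  integ <- apply(corrected[, idx, drop = FALSE], 1,
                 function(x) sum((x[-1] + x[-length(x)]) / 2) * dt)
  wm_mean <- mean(integ[wm_rows])
  if (wm_mean <= 0) stop("white-matter mean bolus integral is nonpositive",
                         call. = FALSE)
  list(rcbv = unname(integ) / wm_mean, window = win, wm_integral = wm_mean)
}

#' 99th-percentile rCBV within the enhancement mask
#'
#' Linear-interpolation percentile (R quantile type 7): for 100 values
#' 1..100 the 99th percentile is 99.01. Returns a non-measurable sentinel
#' (`NA`) when no kept curves intersect the mask.
#'
#' @param rcbv_values rCBV values of kept curves inside the enhancement
#'   mask.
#' @param prob percentile (default 0.99).
#' @export
rcbv99 <- function(rcbv_values, prob = 0.99) {
  x <- rcbv_values[is.finite(rcbv_values)]
  if (length(x) == 0) return(NA_real_)
  stats::quantile(x, prob, names = FALSE, type = 7)
}

#' Percentage of signal recovery
#'
#' `PSR = 100 * (S_post - S_min) / (S_0 - S_min)`, with `S_0` the pre-bolus
#' baseline mean, `S_min` the bolus nadir, and `S_post` the mean of the
#' post-bolus plateau (the final `plateau_frac` of the samples). Values
#' above 100% (signal overshoot from T1-dominant leakage) are legal. Being
#' a ratio of signal differences, PSR is invariant under any affine
#' (gain/offset) rescaling of the whole curve with positive gain.
#'
#' @param curve a `perfusion_curve`.
#' @param plateau_frac fraction of final time points forming the plateau.
#' @return PSR in percent.
#' @export
psr <- function(curve, plateau_frac = 0.25) {
  stopifnot(inherits(curve, "perfusion_curve"))
  s <- curve$signal
  n <- length(s)
  s0 <- mean(s[seq_len(curve$n_baseline)])
  smin <- min(s[(curve$n_baseline + 1):n])
  if (s0 <= smin)
    stop("no bolus dip (baseline <= nadir); curve should have been filtered",
         call. = FALSE)
  tail_idx <- (n - max(1, floor(plateau_frac * n)) + 1):n
  spost <- mean(s[tail_idx])
  100 * (spost - smin) / (s0 - smin)
}

#' @rdname psr
#' @param curves list of kept `perfusion_curve`s inside the enhancement
#'   mask.
#' @export
psr_max <- function(curves, plateau_frac = 0.25) {
  if (length(curves) == 0) return(NA_real_)
  max(vapply(curves, psr, numeric(1), plateau_frac = plateau_frac))
}

#' Perfusion metrics for one patient
#'
#' End-to-end DSC processing on curve matrices: Gaussian-resemblance curve
#' selection within the enhancement mask, delta-R2* conversion, Boxerman
#' leakage correction against the white-matter reference, WM-normalized
#' rCBV, then rCBV-99 and maximum PSR over kept mask curves.
#'
#' @param mask_curves list of `perfusion_curve` sampled in the enhancement
#'   mask.
#' @param wm_curves list of `perfusion_curve` from contralateral white
#'   matter.
#' @param dt time step (s).
#' @param gaussian_r_min curve-selection threshold.
#' @return a `perfusion_metrics` list: `rcbv99`, `psr_max_percent`,
#'   `n_curves_kept`, `n_curves_rejected`.
#' @export
perfusion_metrics <- function(mask_curves, wm_curves, dt = 1,
                              gaussian_r_min = 0.9) {
  filt <- filter_curves(mask_curves, gaussian_r_min = gaussian_r_min)
  n_kept <- length(filt$kept)
  if (n_kept == 0) {
    return(structure(list(rcbv99 = NA_real_, psr_max_percent = NA_real_,
                          n_curves_kept = 0L,
                          n_curves_rejected = length(mask_curves)),
                     class = "perfusion_metrics"))
  }
  nb <- filt$kept[[1]]$n_baseline
  dr2_mask <- t(vapply(filt$kept, delta_r2star,
                       numeric(length(filt$kept[[1]]$signal))))
  dr2_wm <- t(vapply(wm_curves, delta_r2star,
                     numeric(length(wm_curves[[1]]$signal))))
  ref <- colMeans(dr2_wm)
  all_curves <- rbind(dr2_mask, dr2_wm)
  corr <- boxerman_correct(all_curves, ref, dt = dt)
  wm_rows <- n_kept + seq_along(wm_curves)
  rc <- rcbv_map(corr$corrected, wm_rows, reference_curve = ref,
                 n_baseline = nb, dt = dt)
  structure(list(rcbv99 = rcbv99(rc$rcbv[seq_len(n_kept)]),
                 psr_max_percent = psr_max(filt$kept),
                 n_curves_kept = n_kept,
                 n_curves_rejected = length(mask_curves) - n_kept),
            class = "perfusion_metrics")
}
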