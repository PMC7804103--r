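#' Radiomics extraction configuration
#'
#' @param resample_spacing_mm isotropic voxel size for extraction (mm);
#'   `NULL` keeps the native grid.
#' @param bin_width fixed intensity bin width for discretization. The
#'   reproducibility literature favours fixed bin WIDTH; a fixed bin COUNT
#'   mode is provided behind `bin_mode` because some protocols phrase
#'   discretization as "levels".
#' @param bin_mode `"width"` (default) or `"count"`.
#' @param n_bins number of bins when `bin_mode = "count"`.
#' @export
radiomics_config <- function(resample_spacing_mm = 1, bin_width = 10,
                             bin_mode = c("width", "count"), n_bins = 32) {
  bin_mode <- match.arg(bin_mode)
  if (bin_width <= 0) stop("bin_width must be > 0", call. = FALSE)
  if (!is.null(resample_spacing_mm) && any(resample_spacing_mm <= 0))
    stop("resample spacing must be > 0", call. = FALSE)
  structure(list(resample_spacing_mm = resample_spacing_mm,
                 bin_width = bin_width, bin_mode = bin_mode, n_bins = n_bins),
            class = "radiomics_config")
}

# 13 unique 3D direction offsets at Chebyshev distance 1 (one per +/- pair)
unique_offsets_13 <- function() {
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  keep <- apply(offs, 1, function(o) {
    o[3] > 0 || (o[3] == 0 && (o[2] > 0 || (o[2] == 0 && o[1] > 0)))
  })
  offs[keep, , drop = FALSE]
}

# discretize intensities in mask: level(v) = floor((v - min)/bw) + 1
discretize_mask <- function(values, mask, cfg) {
  v <- values[mask]
  if (cfg$bin_mode == "width") {
    lv <- floor((v - min(v)) / cfg$bin_width) + 1
  } else {
    rng <- max(v) - min(v)
    bw <- if (rng == 0) 1 else rng / cfg$n_bins
    lv <- pmin(floor((v - min(v)) / bw) + 1, cfg$n_bins)
  }
  disc <- array(NA_integer_, dim(values))
  disc[mask] <- as.integer(lv)
  disc
}

crop_to_mask <- function(values, mask, margin = 1) {
  idx <- which(mask, arr.ind = TRUE)
  d <- dim(mask)
  lo <- pmax(apply(idx, 2, min) - margin, 1)
  hi <- pmin(apply(idx, 2, max) + margin, d)
  list(values = values[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE],
       mask = mask[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE])
}

shift_array <- function(a, off) {
  d <- dim(a)
  out <- array(NA, d)
  src <- lapply(1:3, function(ax) {
    s <- seq_len(d[ax]) + off[ax]
    s[s < 1 | s > d[ax]] <- NA
    s
  })
  ok <- lapply(src, function(s) which(!is.na(s)))
  out[ok[[1]], ok[[2]], ok[[3]]] <-
    a[src[[1]][ok[[1]]], src[[2]][ok[[2]]], src[[3]][ok[[3]]]]
  out
}

eps_log <- 2.2e-16
log2s <- function(x) log2(x + eps_log)

## ---- first order (19) -------------------------------------------------

firstorder_features <- function(v, disc_levels, voxel_vol_mm3) {
  n <- length(v)
  m <- mean(v)
  varp <- mean((v - m)^2)
  p10 <- stats::quantile(v, 0.10, names = FALSE, type = 7)
  p90 <- stats::quantile(v, 0.90, names = FALSE, type = 7)
  sub <- v[v >= p10 & v <= p90]
  hist_p <- tabulate(disc_levels) / n
  hist_p <- hist_p[hist_p > 0]
  c(firstorder_Energy = sum(v^2),
    firstorder_TotalEnergy = voxel_vol_mm3 * sum(v^2),
    firstorder_Entropy = -sum(hist_p * log2s(hist_p)),
    firstorder_Minimum = min(v),
    firstorder_Percentile10 = p10,
    firstorder_Percentile90 = p90,
    firstorder_Maximum = max(v),
    firstorder_Mean = m,
    firstorder_Median = stats::median(v),
    firstorder_InterquartileRange =
      stats::quantile(v, 0.75, names = FALSE, type = 7) -
      stats::quantile(v, 0.25, names = FALSE, type = 7),
    firstorder_Range = max(v) - min(v),
    firstorder_MeanAbsoluteDeviation = mean(abs(v - m)),
    firstorder_RobustMeanAbsoluteDeviation =
      if (length(sub)) mean(abs(sub - mean(sub))) else 0,
    firstorder_RootMeanSquared = sqrt(mean(v^2)),
    firstorder_StandardDeviation = sqrt(varp),
    firstorder_Skewness =
      if (varp > 0) mean((v - m)^3) / varp^1.5 else 0,
    firstorder_Kurtosis =
      if (varp > 0) mean((v - m)^4) / varp^2 else 0,
    firstorder_Variance = varp,
    firstorder_Uniformity = sum(hist_p^2))
}

## ---- GLCM (24) --------------------------------------------------------

glcm_matrix <- function(disc, off, ng) {
  sh <- shift_array(disc, off)
  ok <- !is.na(disc) & !is.na(sh)
  if (!any(ok)) return(NULL)
  i <- disc[ok]; j <- sh[ok]
  P <- matrix(0, ng, ng)
  tab <- table(factor(i, levels = 1:ng), factor(j, levels = 1:ng))
  P <- P + tab + t(tab)          # symmetric
  P / sum(P)
}

glcm_features_one <- function(P) {
  ng <- nrow(P)
  i <- row(P); j <- col(P)
  px <- rowSums(P); py <- colSums(P)
  mux <- sum((1:ng) * px); muy <- sum((1:ng) * py)
  sigx <- sqrt(sum(((1:ng) - mux)^2 * px))
  sigy <- sqrt(sum(((1:ng) - muy)^2 * py))
  # diagonal and cross-diagonal distributions
  k_diff <- 0:(ng - 1)
  pxmy <- vapply(k_diff, function(k) sum(P[abs(i - j) == k]), numeric(1))
  k_sum <- 2:(2 * ng)
  pxpy <- vapply(k_sum, function(k) sum(P[(i + j) == k]), numeric(1))
  HX <- -sum(px[px > 0] * log2s(px[px > 0]))
  HY <- -sum(py[py > 0] * log2s(py[py > 0]))
  HXY <- -sum(P[P > 0] * log2s(P[P > 0]))
  pxy_outer <- outer(px, py)
  nz <- P > 0
  HXY1 <- -sum(P[nz] * log2s(pxy_outer[nz]))
  nz2 <- pxy_outer > 0
  HXY2 <- -sum(pxy_outer[nz2] * log2s(pxy_outer[nz2]))
  da <- sum(k_diff * pxmy)
  corr <- if (sigx > 0 && sigy > 0)
    (sum(i * j * P) - mux * muy) / (sigx * sigy) else 1
  imc1 <- if (max(HX, HY) > 0) (HXY - HXY1) / max(HX, HY) else 0
  imc2_arg <- 1 - exp(-2 * (HXY2 - HXY))
  imc2 <- sqrt(max(imc2_arg, 0))
  # MCC: second largest eigenvalue of Q
  mcc <- {
    act <- which(px > 0)
    if (length(act) < 2) 1 else {
      Ps <- P[act, act, drop = FALSE]
      pxs <- px[act]; pys <- py[act]
      Q <- (Ps / pxs) %*% t(Ps / matrix(pys, nrow(Ps), ncol(Ps),
                                        byrow = TRUE))
      ev <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
      sqrt(max(ev[2], 0))
    }
  }
  invvar <- sum(P[i != j] / (i[i != j] - j[i != j])^2)
  c(glcm_Autocorrelation = sum(i * j * P),
    glcm_JointAverage = mux,
    glcm_ClusterProminence = sum((i + j - mux - muy)^4 * P),
    glcm_ClusterShade = sum((i + j - mux - muy)^3 * P),
    glcm_ClusterTendency = sum((i + j - mux - muy)^2 * P),
    glcm_Contrast = sum((i - j)^2 * P),
    glcm_Correlation = corr,
    glcm_DifferenceAverage = da,
    glcm_DifferenceEntropy = -sum(pxmy[pxmy > 0] * log2s(pxmy[pxmy > 0])),
    glcm_DifferenceVariance = sum((k_diff - da)^2 * pxmy),
    glcm_JointEnergy = sum(P^2),
    glcm_JointEntropy = HXY,
    glcm_Imc1 = imc1,
    glcm_Imc2 = imc2,
    glcm_Idm = sum(P / (1 + (i - j)^2)),
    glcm_MCC = mcc,
    glcm_Idmn = sum(P / (1 + ((i - j) / ng)^2)),
    glcm_Id = sum(P / (1 + abs(i - j))),
    glcm_Idn = sum(P / (1 + abs(i - j) / ng)),
    glcm_InverseVariance = invvar,
    glcm_MaximumProbability = max(P),
    glcm_SumAverage = sum(k_sum * pxpy),
    glcm_SumEntropy = -sum(pxpy[pxpy > 0] * log2s(pxpy[pxpy > 0])),
    glcm_SumSquares = sum((i - mux)^2 * P))
}

glcm_features <- function(disc, ng) {
  offs <- unique_offsets_13()
  feats <- NULL
  cnt <- 0
  for (r in seq_len(nrow(offs))) {
    P <- glcm_matrix(disc, offs[r, ], ng)
    if (is.null(P)) next
    f <- glcm_features_one(P)
    feats <- if (is.null(feats)) f else feats + f
    cnt <- cnt + 1
  }
  feats / cnt
}

## ---- GLRLM (16) -------------------------------------------------------

# runs of equal gray level along one direction; returns counts by
# (level, run length)
glrlm_runs <- function(disc, off) {
  prev <- shift_array(disc, -off)
  inmask <- !is.na(disc)
  starts <- which(inmask & (is.na(prev) | prev != disc))
  d <- dim(disc)
  runs_i <- integer(0); runs_j <- integer(0)
  coords <- arrayInd(starts, d)
  for (s in seq_along(starts)) {
    pos <- coords[s, ]
    lev <- disc[starts[s]]
    len <- 1L
    repeat {
      nxt <- pos + off
      if (any(nxt < 1) || any(nxt > d)) break
      v <- disc[nxt[1], nxt[2], nxt[3]]
      if (is.na(v) || v != lev) break
      len <- len + 1L
      pos <- nxt
    }
    runs_i <- c(runs_i, lev); runs_j <- c(runs_j, len)
  }
  cbind(level = runs_i, size = runs_j)
}

# shared feature set for level-by-size matrices (GLRLM runs, GLSZM zones,
# GLDM dependencies); `prefix` and `nm` give the family's naming scheme
size_matrix_features <- function(counts, np, prefix, nm) {
  lev <- counts[, 1]; sz <- counts[, 2]; w <- counts[, 3]
  nz <- sum(w)
  p <- w / nz
  mu_i <- sum(p * lev); mu_j <- sum(p * sz)
  gl_marg <- tapply(w, lev, sum)
  sz_marg <- tapply(w, sz, sum)
  out <- c(
    sum(w / sz^2) / nz,                      # small emphasis
    sum(w * sz^2) / nz,                      # large emphasis
    sum(gl_marg^2) / nz,                     # gray level non-uniformity
    sum(gl_marg^2) / nz^2,                   # ... normalized
    sum(sz_marg^2) / nz,                     # size non-uniformity
    sum(sz_marg^2) / nz^2,                   # ... normalized
    nz / np,                                 # percentage
    sum(p * (lev - mu_i)^2),                 # gray level variance
    sum(p * (sz - mu_j)^2),                  # size variance
    -sum(p * log2s(p)),                      # entropy
    sum(w / lev^2) / nz,                     # low gray level
    sum(w * lev^2) / nz,                     # high gray level
    sum(w / (lev^2 * sz^2)) / nz,            # small + low
    sum(w * lev^2 / sz^2) / nz,              # small + high
    sum(w * sz^2 / lev^2) / nz,              # large + low
    sum(w * sz^2 * lev^2) / nz)              # large + high
  names(out) <- paste0(prefix, "_", nm)
  out
}

glrlm_names <- c("ShortRunEmphasis", "LongRunEmphasis",
  "GrayLevelNonUniformity", "GrayLevelNonUniformityNormalized",
  "RunLengthNonUniformity", "RunLengthNonUniformityNormalized",
  "RunPercentage", "GrayLevelVariance", "RunVariance", "RunEntropy",
  "LowGrayLevelRunEmphasis", "HighGrayLevelRunEmphasis",
  "ShortRunLowGrayLevelEmphasis", "ShortRunHighGrayLevelEmphasis",
  "LongRunLowGrayLevelEmphasis", "LongRunHighGrayLevelEmphasis")

glrlm_features <- function(disc) {
  offs <- unique_offsets_13()
  np <- sum(!is.na(disc))
  total <- NULL
  for (r in seq_len(nrow(offs))) {
    runs <- glrlm_runs(disc, offs[r, ])
    agg <- stats::aggregate(list(w = rep(1, nrow(runs))),
                            by = list(level = runs[, 1], size = runs[, 2]),
                            FUN = sum)
    f <- size_matrix_features(as.matrix(agg), np, "glrlm", glrlm_names)
    total <- if (is.null(total)) f else total + f
  }
  total / nrow(offs)
}

## ---- GLSZM (16) -------------------------------------------------------

glszm_names <- c("SmallAreaEmphasis", "LargeAreaEmphasis",
  "GrayLevelNonUniformity", "GrayLevelNonUniformityNormalized",
  "SizeZoneNonUniformity", "SizeZoneNonUniformityNormalized",
  "ZonePercentage", "GrayLevelVariance", "ZoneVariance", "ZoneEntropy",
  "LowGrayLevelZoneEmphasis", "HighGrayLevelZoneEmphasis",
  "SmallAreaLowGrayLevelEmphasis", "SmallAreaHighGrayLevelEmphasis",
  "LargeAreaLowGrayLevelEmphasis", "LargeAreaHighGrayLevelEmphasis")

glszm_features <- function(disc) {
  np <- sum(!is.na(disc))
  levs <- sort(unique(disc[!is.na(disc)]))
  zl <- integer(0); zs <- integer(0)
  for (lv in levs) {
    m <- !is.na(disc) & disc == lv
    lab <- label_components(m, connectivity = 26)
    if (max(lab) == 0) next
    sizes <- tabulate(lab[lab > 0])
    zl <- c(zl, rep(lv, length(sizes)))
    zs <- c(zs, sizes)
  }
  agg <- stats::aggregate(list(w = rep(1, length(zl))),
                          by = list(level = zl, size = zs), FUN = sum)
  size_matrix_features(as.matrix(agg), np, "glszm", glszm_names)
}

## ---- NGTDM (5) --------------------------------------------------------

ngtdm_features <- function(disc) {
  d <- dim(disc)
  inmask <- !is.na(disc)
  nv <- sum(inmask)
  # 26-neighbour sums and counts within the mask
  nb_sum <- array(0, d); nb_cnt <- array(0, d)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  vals <- disc; vals[!inmask] <- 0
  msk <- inmask * 1
  for (r in seq_len(nrow(offs))) {
    nb_sum <- nb_sum + shift_na0(vals, offs[r, ])
    nb_cnt <- nb_cnt + shift_na0(msk, offs[r, ])
  }
  has_nb <- inmask & nb_cnt > 0
  abar <- nb_sum[has_nb] / nb_cnt[has_nb]
  lev <- disc[has_nb]
  levs <- sort(unique(lev))
  n_i <- vapply(levs, function(l) sum(lev == l), numeric(1))
  s_i <- vapply(levs, function(l) sum(abs(l - abar[lev == l])), numeric(1))
  p_i <- n_i / sum(n_i)
  ngp <- length(levs)
  sum_ps <- sum(p_i * s_i)
  coarseness <- if (sum_ps > 0) 1 / sum_ps else 1e6
  if (ngp > 1) {
    ij <- expand.grid(a = seq_len(ngp), b = seq_len(ngp))
    pij <- p_i[ij$a] * p_i[ij$b]
    dij <- (levs[ij$a] - levs[ij$b])^2
    contrast <- sum(pij * dij) / (ngp * (ngp - 1)) * sum(s_i) / sum(n_i)
    busy_den <- sum(abs(levs[ij$a] * p_i[ij$a] - levs[ij$b] * p_i[ij$b]))
    busyness <- if (busy_den > 0) sum_ps / busy_den else 0
    complexity <- sum(abs(levs[ij$a] - levs[ij$b]) *
                      (p_i[ij$a] * s_i[ij$a] + p_i[ij$b] * s_i[ij$b]) /
                      (p_i[ij$a] + p_i[ij$b])) / sum(n_i)
    strength <- if (sum(s_i) > 0)
      sum((p_i[ij$a] + p_i[ij$b]) * dij) / sum(s_i) else 0
  } else {
    contrast <- 0; busyness <- 0; complexity <- 0; strength <- 0
  }
  c(ngtdm_Coarseness = coarseness, ngtdm_Contrast = contrast,
    ngtdm_Busyness = busyness, ngtdm_Complexity = complexity,
    ngtdm_Strength = strength)
}

shift_na0 <- function(a, off) {
  s <- shift_array(a, off)
  s[is.na(s)] <- 0
  s
}

## ---- GLDM (14) --------------------------------------------------------

gldm_names <- c("SmallDependenceEmphasis", "LargeDependenceEmphasis",
  "GrayLevelNonUniformity", "DependenceNonUniformity",
  "DependenceNonUniformityNormalized", "GrayLevelVariance",
  "DependenceVariance", "DependenceEntropy", "LowGrayLevelEmphasis",
  "HighGrayLevelEmphasis", "SmallDependenceLowGrayLevelEmphasis",
  "SmallDependenceHighGrayLevelEmphasis",
  "LargeDependenceLowGrayLevelEmphasis",
  "LargeDependenceHighGrayLevelEmphasis")

gldm_features <- function(disc, alpha = 0) {
  inmask <- !is.na(disc)
  np <- sum(inmask)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  dep <- array(0, dim(disc))
  for (r in seq_len(nrow(offs))) {
    sh <- shift_array(disc, offs[r, ])
    dep <- dep + (!is.na(sh) & inmask & abs(sh - disc) <= alpha)
  }
  lev <- disc[inmask]
  size <- dep[inmask] + 1    # dependence size includes the center voxel
  agg <- stats::aggregate(list(w = rep(1, length(lev))),
                          by = list(level = lev, size = size), FUN = sum)
  f16 <- size_matrix_features(as.matrix(agg), np, "gldm", glrlm_names)
  # the canonical 14-feature set drops the two normalized-GLN variants:
  # keep SDE, LDE, GLN, DN, DNN, GLV, DV, DE, LGLE, HGLE, SDLGLE, SDHGLE,
  # LDLGLE, LDHGLE. In the 16-vector these are positions
  # 1,2,3,5,6,8,9,10,11,12,13,14,15,16 (drop GLNN [4] and percentage [7]).
  out <- unname(f16[c(1:3, 5, 6, 8:16)])
  names(out) <- paste0("gldm_", gldm_names)
  out
}

## ---- extraction entry points ------------------------------------------

#' Extract the 94-feature radiomics vector
#'
#' Resamples image and mask to the configured isotropic spacing (linear /
#' nearest-neighbour), discretizes intensities with a fixed bin width
#' anchored at the mask minimum, and computes six feature families per the
#' image biomarker standardization conventions: first-order (19), GLCM (24,
#' symmetric, averaged over the 13 unique 3D directions at distance 1),
#' GLRLM (16, averaged over directions), GLSZM (16, 26-connected zones),
#' NGTDM (5, 26-neighbourhood), GLDM (14, dependence alpha = 0).
#'
#' @param t1wc a [volume3d] intensity image.
#' @param mask an `enhancement_mask` on the same grid.
#' @param cfg a [radiomics_config].
#' @return named numeric vector of length 94 with attribute `family`
#'   (factor of family names), or a non-measurable sentinel (`NULL`) if
#'   the mask vanishes after resampling.
#' @export
extract_features <- function(t1wc, mask, cfg = radiomics_config()) {
  stopifnot(is_volume3d(t1wc), inherits(mask, "enhancement_mask"))
  mv <- volume3d(mask$mask * 1, mask$spacing_mm, t1wc$origin_mm)
  if (!is.null(cfg$resample_spacing_mm) &&
      !all(abs(rep_len(cfg$resample_spacing_mm, 3) - t1wc$spacing_mm) <
             1e-9)) {
    t1wc <- resample(t1wc, cfg$resample_spacing_mm, "linear")
    mv <- resample(mv, cfg$resample_spacing_mm, "nearest")
  }
  m <- mv$values > 0.5
  if (sum(m) < 2) return(NULL)      # non-measurable after resampling
  cr <- crop_to_mask(t1wc$values, m)
  disc <- discretize_mask(cr$values, cr$mask, cfg)
  ng <- max(disc, na.rm = TRUE)
  v <- cr$values[cr$mask]
  feats <- c(
    firstorder_features(v, disc[cr$mask], prod(t1wc$spacing_mm)),
    glcm_features(disc, ng),
    glrlm_features(disc),
    glszm_features(disc),
    ngtdm_features(disc),
    gldm_features(disc))
  fam <- sub("_.*", "", names(feats))
  attr(feats, "family") <- factor(fam,
    levels = c("firstorder", "glcm", "glrlm", "glszm", "ngtdm", "gldm"))
  feats
}

#' Robustness screening under extraction-parameter perturbation
#'
#' Re-extracts the feature vector across a perturbation grid of
#' (resampling spacing, bin width) and computes each feature's coefficient
#' of variation, `CoV = 100 * sd / |mean|`. Features with CoV below
#' `cov_threshold` are flagged robust; features whose mean across
#' perturbations is 0 cannot have a CoV and are flagged separately.
#'
#' @param t1wc,mask,cfg as in [extract_features()].
#' @param perturbations list of `c(spacing, bin_width)` pairs; default
#'   spacing {1, 2} mm x bin width {5, 10, 20}.
#' @param cov_threshold robustness cut-off in percent (default 20).
#' @return a data.frame with `feature`, `family`, `cov_percent`, `robust`,
#'   `zero_mean`.
#' @export
robustness_screen <- function(t1wc, mask, cfg = radiomics_config(),
                              perturbations = NULL, cov_threshold = 20) {
  if (is.null(perturbations))
    perturbations <- expand_perturbations(c(1, 2), c(5, 10, 20))
  if (length(perturbations) < 2)
    stop("need at least two perturbations", call. = FALSE)
  mats <- lapply(perturbations, function(p) {
    cfg_p <- radiomics_config(resample_spacing_mm = p[1], bin_width = p[2],
                              bin_mode = cfg$bin_mode, n_bins = cfg$n_bins)
    extract_features(t1wc, mask, cfg_p)
  })
  ok <- !vapply(mats, is.null, logical(1))
  mats <- mats[ok]
  if (length(mats) < 2)
    stop("mask vanished under all but one perturbation", call. = FALSE)
  M <- do.call(rbind, mats)
  mu <- colMeans(M)
  sdv <- apply(M, 2, stats::sd)
  zero <- mu == 0
  cov <- ifelse(zero, NA_real_, 100 * sdv / abs(mu))
  data.frame(feature = colnames(M),
             family = sub("_.*", "", colnames(M)),
             cov_percent = cov,
             robust = !zero & cov < cov_threshold,
             zero_mean = zero,
             row.names = NULL, stringsAsFactors = FALSE)
}

expand_perturbations <- function(spacings, bin_widths) {
  g <- expand.grid(sp = spacings, bw = bin_widths)
  lapply(seq_len(nrow(g)), function(i) c(g$sp[i], g$bw[i]))
}
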