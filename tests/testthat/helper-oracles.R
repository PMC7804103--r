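# Independent oracles used by the dual-route tests. These deliberately share
# no code with the package internals: brute-force enumeration throughout.

# Exhaustive nearest-background Euclidean distance for every foreground
# voxel, honoring anisotropic spacing; the grid is padded by one layer of
# background outside each face (same convention the package documents).
brute_force_edt <- function(mask, spacing) {
  d <- dim(mask)
  fg <- which(mask, arr.ind = TRUE)
  bg <- which(!mask, arr.ind = TRUE)
  faces <- list()
  for (ax in 1:3) for (side in c(0L, d[ax] + 1L)) {
    g <- expand.grid(i = if (ax == 1) side else seq_len(d[1]),
                     j = if (ax == 2) side else seq_len(d[2]),
                     k = if (ax == 3) side else seq_len(d[3]))
    faces[[length(faces) + 1]] <- as.matrix(g)
  }
  bg_all <- rbind(bg, do.call(rbind, faces))
  out <- array(0, d)
  bx <- bg_all[, 1] * spacing[1]
  by <- bg_all[, 2] * spacing[2]
  bz <- bg_all[, 3] * spacing[3]
  for (r in seq_len(nrow(fg))) {
    d2 <- (bx - fg[r, 1] * spacing[1])^2 +
          (by - fg[r, 2] * spacing[2])^2 +
          (bz - fg[r, 3] * spacing[3])^2
    out[fg[r, 1], fg[r, 2], fg[r, 3]] <- sqrt(min(d2))
  }
  out
}

# AUC as the brute-force fraction of concordant positive/negative pairs
# (ties count one half)
brute_force_auc <- function(scores, outcomes) {
  pos <- scores[outcomes == 1]
  neg <- scores[outcomes == 0]
  tot <- 0
  for (p in pos) for (n in neg)
    tot <- tot + (p > n) + 0.5 * (p == n)
  tot / (length(pos) * length(neg))
}

# Hand product-limit estimator: returns data.frame of event times and
# survival estimates for one group
hand_km <- function(time, event) {
  ord <- order(time)
  time <- time[ord]; event <- event[ord]
  ev_times <- sort(unique(time[event == 1]))
  s <- 1
  out <- data.frame(time = numeric(0), surv = numeric(0))
  for (tt in ev_times) {
    n_risk <- sum(time >= tt)
    n_ev <- sum(time == tt & event == 1)
    s <- s * (1 - n_ev / n_risk)
    out <- rbind(out, data.frame(time = tt, surv = s))
  }
  out
}

# Hand two-group log-rank chi-square statistic
hand_logrank <- function(time, event, group) {
  ev_times <- sort(unique(time[event == 1]))
  O <- 0; E <- 0; V <- 0
  for (tt in ev_times) {
    at_risk <- time >= tt
    n <- sum(at_risk)
    n1 <- sum(at_risk & group == 1)
    d <- sum(time == tt & event == 1)
    d1 <- sum(time == tt & event == 1 & group == 1)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (O - E)^2 / V
}

# BH step-up adjustment from the definition: p_adj(i) = min_{j>=i} m p(j)/j
hand_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  adj <- numeric(m)
  for (i in seq_len(m))
    adj[i] <- min(1, min(m * ps[i:m] / (i:m)))
  out <- numeric(m)
  out[ord] <- adj
  out
}

# Brute-force symmetric normalized GLCM for one offset over a discretized
# array (NA outside mask), by explicit voxel-pair loops
brute_glcm <- function(disc, off, ng) {
  d <- dim(disc)
  P <- matrix(0, ng, ng)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    a <- disc[i, j, k]
    if (is.na(a)) next
    ii <- i + off[1]; jj <- j + off[2]; kk <- k + off[3]
    if (ii < 1 || ii > d[1] || jj < 1 || jj > d[2] || kk < 1 || kk > d[3])
      next
    b <- disc[ii, jj, kk]
    if (is.na(b)) next
    P[a, b] <- P[a, b] + 1
    P[b, a] <- P[b, a] + 1
  }
  P / sum(P)
}

# Brute-force run-length counts along one direction by walking every voxel
brute_glrlm_runs <- function(disc, off) {
  d <- dim(disc)
  runs <- list()
  inb <- function(p) all(p >= 1) && all(p <= d)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    p <- c(i, j, k)
    v <- disc[i, j, k]
    if (is.na(v)) next
    prev <- p - off
    if (inb(prev) && !is.na(disc[prev[1], prev[2], prev[3]]) &&
        disc[prev[1], prev[2], prev[3]] == v) next   # not a run start
    len <- 1
    q <- p + off
    while (inb(q) && !is.na(disc[q[1], q[2], q[3]]) &&
           disc[q[1], q[2], q[3]] == v) {
      len <- len + 1
      q <- q + off
    }
    runs[[length(runs) + 1]] <- c(v, len)
  }
  do.call(rbind, runs)
}

# number of voxel centers inside a spherical shell, by exhaustive scan
brute_shell_voxels <- function(grid_shape, spacing, center, r_in, r_out) {
  cnt <- 0
  for (i in seq_len(grid_shape[1])) for (j in seq_len(grid_shape[2]))
    for (k in seq_len(grid_shape[3])) {
      p <- (c(i, j, k) - 0.5) * spacing
      dd <- sqrt(sum((p - center)^2))
      if (dd >= r_in && dd < r_out) cnt <- cnt + 1
    }
  cnt
}

# small random mask guaranteed nonempty
random_mask <- function(dims, fg_frac) {
  m <- array(stats::runif(prod(dims)) < fg_frac, dims)
  if (!any(m)) m[ceiling(dims[1] / 2), ceiling(dims[2] / 2),
                 ceiling(dims[3] / 2)] <- TRUE
  m
}
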