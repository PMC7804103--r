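#' Dichotomize overall survival at a fixed endpoint
#'
#' Patients with survival beyond the endpoint are "long" survivors; events
#' before it are "short". Patients censored before the endpoint carry an
#' exclusion flag: they are removed from logistic/ROC analyses but kept in
#' Cox and Kaplan-Meier analyses.
#'
#' @param records cohort data.frame with `os_days`, `os_event`.
#' @param endpoint_days dichotomization endpoint (default 2 years).
#' @return `records` with added columns `os_long` (1 = long, 0 = short,
#'   NA = excluded) and `dichot_excluded`.
#' @export
dichotomize_survival <- function(records, endpoint_days = 730) {
  long <- ifelse(records$os_days >= endpoint_days, 1L,
                 ifelse(records$os_event == 1, 0L, NA_integer_))
  records$os_long <- long
  records$dichot_excluded <- is.na(long)
  records
}

#' Stratified training/test split
#'
#' Splits on the dichotomized outcome so the long/short proportions in the
#' training and test sets match within one patient. Deterministic given
#' the seed.
#'
#' @param records data.frame with an `os_long` column (see
#'   [dichotomize_survival()]); excluded rows are dropped first.
#' @param train_frac training fraction (default 0.7).
#' @param seed integer seed.
#' @return list with `train` and `test` data.frames.
#' @export
split_cohort <- function(records, train_frac = 0.7, seed = 1L) {
  if (!"os_long" %in% names(records))
    stop("records must carry `os_long`; call dichotomize_survival() first",
         call. = FALSE)
  elig <- records[!is.na(records$os_long), , drop = FALSE]
  classes <- split(seq_len(nrow(elig)), elig$os_long)
  if (any(vapply(classes, length, integer(1)) < 2))
    stop("each outcome class needs >= 2 patients to stratify", call. = FALSE)
  rng <- local_rng(seed)
  train_idx <- unlist(lapply(classes, function(ix) {
    n_tr <- round(train_frac * length(ix))
    rng$sample(ix, n_tr)
  }))
  list(train = elig[sort(train_idx), , drop = FALSE],
       test = elig[setdiff(seq_len(nrow(elig)), train_idx), , drop = FALSE])
}

#' Z-score feature normalization with training statistics
#'
#' Features are centered and scaled by the TRAINING set's mean and standard
#' deviation; the same scaler is applied to the test set. Zero-variance
#' features are dropped with a warning.
#'
#' @param train,test data.frames.
#' @param feature_cols names of columns to normalize.
#' @return list with `train`, `test`, `scaler` (`center`/`scale` per kept
#'   feature) and `dropped`.
#' @export
normalize_features <- function(train, test, feature_cols) {
  mu <- vapply(feature_cols, function(f) mean(train[[f]]), numeric(1))
  sdv <- vapply(feature_cols, function(f) stats::sd(train[[f]]), numeric(1))
  dropped <- feature_cols[sdv == 0 | !is.finite(sdv)]
  if (length(dropped))
    warning("dropping zero-variance feature(s): ",
            paste(dropped, collapse = ", "), call. = FALSE)
  keep <- setdiff(feature_cols, dropped)
  for (f in keep) {
    train[[f]] <- (train[[f]] - mu[f]) / sdv[f]
    test[[f]] <- (test[[f]] - mu[f]) / sdv[f]
  }
  list(train = train, test = test,
       scaler = list(center = mu[keep], scale = sdv[keep]),
       dropped = dropped)
}

## ---- mutual information / mRMR ----------------------------------------

# plug-in mutual information between two discrete vectors (log base 2)
mutual_information <- function(x, y) {
  tab <- table(x, y)
  p <- tab / sum(tab)
  px <- rowSums(p); py <- colSums(p)
  nz <- p > 0
  sum(p[nz] * log2(p[nz] / outer(px, py)[nz]))
}

# quantile discretization into `bins` levels (terciles by default)
discretize_quantiles <- function(x, bins = 3) {
  if (length(unique(x)) <= bins) return(as.integer(factor(x)))
  br <- unique(stats::quantile(x, seq(0, 1, length.out = bins + 1),
                               names = FALSE, type = 7))
  cut(x, breaks = br, include.lowest = TRUE, labels = FALSE)
}

#' Minimum-redundancy-maximum-relevance feature selection
#'
#' Greedy mRMR: the first feature maximizes mutual information with the
#' outcome; each subsequent feature maximizes
#' `MI(feature; outcome) - mean MI(feature; selected)`. MI is estimated on
#' quantile-discretized features (terciles by default). Ties are broken by
#' lexicographic feature name, deterministically.
#'
#' @param data data.frame of candidate features.
#' @param outcome binary (or discrete) outcome vector.
#' @param k number of features to select.
#' @param bins discretization bins for MI estimation.
#' @return character vector of selected feature names, in selection order,
#'   with attribute `scores`.
#' @export
mrmr_select <- function(data, outcome, k, bins = 3) {
  feats <- names(data)
  if (k > length(feats)) stop("k exceeds number of features", call. = FALSE)
  disc <- lapply(data, discretize_quantiles, bins = bins)
  rel <- vapply(disc, mutual_information, numeric(1), y = outcome)
  selected <- character(0)
  scores <- numeric(0)
  # precomputed pairwise redundancy, filled lazily
  red_cache <- matrix(NA_real_, length(feats), length(feats),
                      dimnames = list(feats, feats))
  for (step in seq_len(k)) {
    cand <- setdiff(feats, selected)
    crit <- vapply(cand, function(f) {
      if (length(selected) == 0) return(rel[f])
      reds <- vapply(selected, function(s) {
        if (is.na(red_cache[f, s]))
          red_cache[f, s] <<- mutual_information(disc[[f]], disc[[s]])
        red_cache[f, s]
      }, numeric(1))
      rel[f] - mean(reds)
    }, numeric(1))
    ord <- order(-crit, cand)       # ties: lexicographic name
    best <- cand[ord[1]]
    selected <- c(selected, best)
    scores <- c(scores, crit[ord[1]])
  }
  attr(selected, "scores") <- scores
  selected
}

#' Bidirectional stepwise logistic regression on AIC
#'
#' Starts from the intercept-only model and steps (both directions) over
#' the candidate features using AIC. If quasi-separation is detected
#' (divergent coefficients), the final model is refit with a ridge penalty
#' and a warning is raised.
#'
#' @param train data.frame containing the outcome and candidates.
#' @param outcome_col name of the binary outcome column.
#' @param candidates character vector of candidate feature names.
#' @return a `selection_result`: list with `selected`, `model` (glm),
#'   `coefficients`, `aic`, `separation`.
#' @export
stepwise_logistic <- function(train, outcome_col, candidates) {
  if (length(candidates) < 1) stop("need at least one candidate",
                                   call. = FALSE)
  df <- train[, c(outcome_col, candidates), drop = FALSE]
  null_fm <- stats::as.formula(paste(outcome_col, "~ 1"))
  full_fm <- stats::as.formula(
    paste(outcome_col, "~", paste(candidates, collapse = " + ")))
  fit0 <- stats::glm(null_fm, family = stats::binomial(), data = df)
  fit <- suppressWarnings(
    stats::step(fit0, scope = list(lower = null_fm, upper = full_fm),
                direction = "both", trace = 0))
  sel <- setdiff(names(stats::coef(fit)), "(Intercept)")
  sep <- any(abs(stats::coef(fit)) > 10)
  if (sep && length(sel) > 0) {
    warning("possible separation; refitting with ridge penalty",
            call. = FALSE)
    fit <- ridge_logistic(df, outcome_col, sel)
  }
  structure(list(selected = sel, model = fit,
                 coefficients = stats::coef(fit), aic = stats::AIC(fit),
                 separation = sep),
            class = "selection_result")
}

# light ridge-penalized logistic refit via iterated weighted least squares
ridge_logistic <- function(df, outcome_col, sel, lambda = 1e-2) {
  X <- cbind(1, as.matrix(df[, sel, drop = FALSE]))
  y <- df[[outcome_col]]
  beta <- rep(0, ncol(X))
  for (it in 1:50) {
    eta <- as.numeric(X %*% beta)
    p <- 1 / (1 + exp(-eta))
    w <- pmax(p * (1 - p), 1e-8)
    z <- eta + (y - p) / w
    pen <- diag(c(0, rep(lambda, length(sel))))
    beta_new <- solve(crossprod(X * sqrt(w)) + pen,
                      crossprod(X, w * z))
    if (max(abs(beta_new - beta)) < 1e-8) { beta <- beta_new; break }
    beta <- beta_new
  }
  beta <- as.numeric(beta)
  names(beta) <- c("(Intercept)", sel)
  eta <- as.numeric(X %*% beta)
  p <- 1 / (1 + exp(-eta))
  ll <- sum(y * log(pmax(p, 1e-12)) + (1 - y) * log(pmax(1 - p, 1e-12)))
  structure(list(coefficients = beta, fitted.values = p,
                 aic = -2 * ll + 2 * length(beta), ridge = TRUE,
                 formula_vars = sel),
            class = "ridge_logistic")
}

#' @export
coef.ridge_logistic <- function(object, ...) object$coefficients

#' Univariate or multivariate Cox proportional hazards fit
#'
#' Partial-likelihood fit (Efron tie handling) returning the hazard ratio
#' per unit covariate with 95% Wald confidence interval and p-value.
#'
#' @param records cohort data.frame.
#' @param covariates character vector of covariate column names (length 1
#'   for a univariate fit).
#' @param endpoint `"OS"` or `"PFS"` (expects `os_days`/`os_event` or
#'   `pfs_days`/`pfs_event` columns).
#' @return a `cox_result` data.frame: one row per covariate with `hr`,
#'   `ci_lower`, `ci_upper`, `p`, `n`, `n_events`.
#' @export
cox_fit <- function(records, covariates, endpoint = c("OS", "PFS")) {
  endpoint <- match.arg(endpoint)
  tcol <- if (endpoint == "OS") "os_days" else "pfs_days"
  ecol <- if (endpoint == "OS") "os_event" else "pfs_event"
  df <- records[stats::complete.cases(records[, c(tcol, ecol, covariates)]), ]
  if (sum(df[[ecol]]) < 2) stop("need >= 2 events for a Cox fit",
                                call. = FALSE)
  fm <- stats::as.formula(paste0("survival::Surv(", tcol, ", ", ecol,
                                 ") ~ ", paste(covariates, collapse = " + ")))
  fit <- survival::coxph(fm, data = df, ties = "efron")
  s <- summary(fit)
  out <- data.frame(covariate = rownames(s$coefficients),
                    hr = s$coefficients[, "exp(coef)"],
                    ci_lower = s$conf.int[, "lower .95"],
                    ci_upper = s$conf.int[, "upper .95"],
                    p = s$coefficients[, "Pr(>|z|)"],
                    n = nrow(df), n_events = sum(df[[ecol]]),
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("cox_result", "data.frame")
  attr(out, "fit") <- fit
  out
}

#' Kaplan-Meier curves and log-rank test for a dichotomized covariate
#'
#' @param records cohort data.frame.
#' @param covariate column to threshold.
#' @param threshold strata are `covariate > threshold` vs `<= threshold`.
#' @param endpoint `"OS"` or `"PFS"`.
#' @return list with `fit` (a `survfit`), `chisq`, `p`, `strata_n`.
#' @export
km_logrank <- function(records, covariate, threshold,
                       endpoint = c("OS", "PFS")) {
  endpoint <- match.arg(endpoint)
  tcol <- if (endpoint == "OS") "os_days" else "pfs_days"
  ecol <- if (endpoint == "OS") "os_event" else "pfs_event"
  grp <- factor(ifelse(records[[covariate]] > threshold, "high", "low"),
                levels = c("low", "high"))
  if (any(table(grp) == 0)) stop("threshold yields an empty stratum",
                                 call. = FALSE)
  df <- data.frame(time = records[[tcol]], event = records[[ecol]],
                   group = grp)
  fit <- survival::survfit(survival::Surv(time, event) ~ group, data = df)
  lr <- survival::survdiff(survival::Surv(time, event) ~ group, data = df)
  p <- stats::pchisq(lr$chisq, df = 1, lower.tail = FALSE)
  list(fit = fit, chisq = unname(lr$chisq), p = p,
       strata_n = table(grp))
}

#' Empirical ROC curve, AUC with DeLong inference, and Youden threshold
#'
#' AUC is the Mann-Whitney concordance probability (ties count 1/2); its
#' standard error and the p-value against AUC = 0.5 use DeLong's
#' placement-value method. The Youden threshold maximizes
#' `sensitivity + specificity - 1`; ties resolve to the lowest threshold.
#' Predicted-positive means score strictly above the threshold.
#'
#' @param scores numeric model scores.
#' @param outcomes binary outcomes (1 = positive class).
#' @return a `roc_result`: list with `auc`, `ci` (95%), `p`,
#'   `youden_threshold`, `sensitivity`, `specificity`, `n_pos`, `n_neg`.
#' @export
roc_youden <- function(scores, outcomes) {
  outcomes <- as.integer(outcomes)
  pos <- scores[outcomes == 1]
  neg <- scores[outcomes == 0]
  n1 <- length(pos); n0 <- length(neg)
  if (n1 == 0 || n0 == 0) stop("both outcome classes must be present",
                               call. = FALSE)
  # placements
  vx <- vapply(pos, function(x) (sum(x > neg) + 0.5 * sum(x == neg)) / n0,
               numeric(1))
  vy <- vapply(neg, function(y) (sum(pos > y) + 0.5 * sum(pos == y)) / n1,
               numeric(1))
  auc <- mean(vx)
  se <- sqrt(stats::var(vx) / n1 + stats::var(vy) / n0)
  ci <- pmin(pmax(auc + c(-1, 1) * 1.96 * se, 0), 1)
  p <- if (se > 0) 2 * stats::pnorm(-abs(auc - 0.5) / se) else
    as.numeric(auc == 0.5)
  # threshold sweep over midpoint-free unique scores
  thr_cand <- sort(unique(scores))
  youden <- vapply(thr_cand, function(th) {
    sens <- mean(pos > th)
    spec <- mean(neg <= th)
    sens + spec - 1
  }, numeric(1))
  best <- which(youden == max(youden))[1]   # lowest threshold on ties
  th <- thr_cand[best]
  structure(list(auc = auc, ci = ci, p = p, se = se,
                 youden_threshold = th,
                 sensitivity = mean(pos > th), specificity = mean(neg <= th),
                 n_pos = n1, n_neg = n0),
            class = "roc_result")
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment,
#' `p_adj(i) = min_{j >= i} m * p(j) / j` on the sorted p-values (capped at
#' 1). Backed by [stats::p.adjust()]; kept as a named operation because the
#' subgroup analysis contract depends on it.
#'
#' @param p numeric vector of raw p-values.
#' @return adjusted p-values in the original order.
#' @export
bh_adjust <- function(p) stats::p.adjust(p, method = "BH")

#' Per-scan-delay-window Cox subgroup analysis
#'
#' One Cox fit per scan-delay window per covariate; within each covariate
#' family the four window p-values are Benjamini-Hochberg adjusted
#' (`adjust_scope = "per_covariate"`, the default) or all rows are adjusted
#' as one family (`"global"`). Windows with fewer than `min_events` events
#' are flagged unstable; empty windows are skipped with a log entry.
#'
#' @param records cohort data.frame with `scan_delay_group`.
#' @param covariates covariate column names.
#' @param endpoint `"OS"` or `"PFS"`.
#' @param adjust_scope `"per_covariate"` or `"global"`.
#' @param min_events stability flag threshold (default 10).
#' @return data.frame with one row per covariate x window (plus an "All"
#'   row per covariate): `covariate`, `window`, `n`, `n_events`, `hr`,
#'   `ci_lower`, `ci_upper`, `p`, `p_adj`, `unstable`, `significant`.
#' @export
subgroup_analysis <- function(records, covariates, endpoint = "OS",
                              adjust_scope = c("per_covariate", "global"),
                              min_events = 10) {
  adjust_scope <- match.arg(adjust_scope)
  rows <- list()
  skipped <- character(0)
  for (cv in covariates) {
    all_fit <- cox_fit(records, cv, endpoint)
    rows[[length(rows) + 1]] <- data.frame(
      covariate = cv, window = "All", n = all_fit$n,
      n_events = all_fit$n_events, hr = all_fit$hr,
      ci_lower = all_fit$ci_lower, ci_upper = all_fit$ci_upper,
      p = all_fit$p, stringsAsFactors = FALSE)
    for (w in scan_delay_levels) {
      sub <- records[records$scan_delay_group == w, , drop = FALSE]
      if (nrow(sub) == 0 || sum(sub$os_event) < 2) {
        skipped <- c(skipped, paste(cv, w, sep = ":"))
        next
      }
      f <- tryCatch(cox_fit(sub, cv, endpoint), error = function(e) NULL)
      if (is.null(f)) { skipped <- c(skipped, paste(cv, w, sep = ":")); next }
      rows[[length(rows) + 1]] <- data.frame(
        covariate = cv, window = w, n = f$n, n_events = f$n_events,
        hr = f$hr, ci_lower = f$ci_lower, ci_upper = f$ci_upper, p = f$p,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$p_adj <- NA_real_
  win_rows <- out$window != "All"
  if (adjust_scope == "per_covariate") {
    for (cv in covariates) {
      ix <- which(win_rows & out$covariate == cv)
      out$p_adj[ix] <- bh_adjust(out$p[ix])
    }
  } else {
    out$p_adj[win_rows] <- bh_adjust(out$p[win_rows])
  }
  out$p_adj[!win_rows] <- out$p[!win_rows]
  out$unstable <- out$n_events < min_events
  out$significant <- out$p_adj < 0.05
  attr(out, "skipped") <- skipped
  out
}

#' Nested prognostic model family with test-set validation
#'
#' Fits the nested logistic model family — clinical-only (age, KPS),
#' perfusion (rCBV-99, max PSR), thickness, radiomics score, and
#' all-combined — on the training set and evaluates each model's AUC on
#' the held-out test set. Rows with missing features for a given model are
#' dropped (count logged in the result).
#'
#' @param train,test data.frames with `os_long` and feature columns.
#' @param model_specs named list of character vectors of feature columns;
#'   defaults to the five-family layout when the columns exist.
#' @param min_rows minimum complete-case rows per model.
#' @return named list of `roc_result`s (attribute `n_dropped` per model).
#' @export
combined_model <- function(train, test, model_specs = NULL, min_rows = 10) {
  if (is.null(model_specs)) {
    cand <- list(
      clinical = c("age_years", "kps_high"),
      perfusion = c("rcbv99", "psr_max_percent"),
      thickness = "mean_thickness_mm",
      radiomics = "radiomics_score")
    cand <- Filter(function(v) all(v %in% names(train)), cand)
    cand$combined <- unique(unlist(cand))
    model_specs <- cand
  }
  out <- list()
  for (nm in names(model_specs)) {
    vars <- model_specs[[nm]]
    tr <- train[stats::complete.cases(train[, c("os_long", vars)]), ,
                drop = FALSE]
    te <- test[stats::complete.cases(test[, c("os_long", vars)]), ,
               drop = FALSE]
    if (nrow(tr) < min_rows || nrow(te) < 2 ||
        length(unique(te$os_long)) < 2) {
      out[[nm]] <- NULL
      next
    }
    fm <- stats::as.formula(paste("os_long ~", paste(vars, collapse = " + ")))
    fit <- suppressWarnings(stats::glm(fm, family = stats::binomial(),
                                       data = tr))
    sc <- stats::predict(fit, newdata = te, type = "link")
    r <- roc_youden(sc, te$os_long)
    attr(r, "n_dropped") <- (nrow(train) - nrow(tr)) +
      (nrow(test) - nrow(te))
    out[[nm]] <- r
  }
  out
}
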