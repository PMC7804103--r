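make_dichot_cohort <- function(n = 100, n_long = 28, seed = 1) {
  set.seed(seed)
  data.frame(id = sprintf("P%03d", 1:n),
             os_days = c(stats::runif(n_long, 731, 2000),
                         stats::runif(n - n_long, 30, 729)),
             os_event = 1L,
             f1 = stats::rnorm(n), f2 = stats::rnorm(n),
             stringsAsFactors = FALSE)
}

test_that("dichotomization and the stratified split contract", {
  rec <- make_dichot_cohort()
  rec$os_event[50] <- 0L; rec$os_days[50] <- 400  # censored before 2 years
  rec <- dichotomize_survival(rec)
  expect_true(rec$dichot_excluded[50])
  expect_equal(sum(rec$os_long == 1, na.rm = TRUE), 28)

  sp <- split_cohort(rec, train_frac = 0.7, seed = 3)
  n_el <- sum(!rec$dichot_excluded)
  expect_equal(nrow(sp$train) + nrow(sp$test), n_el)
  expect_length(intersect(sp$train$id, sp$test$id), 0)
  # stratification arithmetic: about 70/30 with about 20/8 long survivors
  expect_equal(nrow(sp$train), round(0.7 * 28) + round(0.7 * (n_el - 28)))
  expect_equal(sum(sp$train$os_long), round(0.7 * 28))
  # class proportions match within one patient of perfect stratification
  expect_lt(abs(mean(sp$train$os_long) - mean(sp$test$os_long)),
            1 / min(nrow(sp$train), nrow(sp$test)) + 0.04)

  # deterministic given seed
  sp2 <- split_cohort(rec, train_frac = 0.7, seed = 3)
  expect_identical(sp$train$id, sp2$train$id)
})

test_that("feature normalization uses training statistics only", {
  rec <- dichotomize_survival(make_dichot_cohort(seed = 2))
  rec$konst <- 5
  sp <- split_cohort(rec, seed = 1)
  expect_warning(
    nm <- normalize_features(sp$train, sp$test, c("f1", "f2", "konst")),
    "konst")
  expect_equal(mean(nm$train$f1), 0, tolerance = 1e-12)
  expect_equal(stats::sd(nm$train$f1), 1, tolerance = 1e-12)
  # test set scaled with training stats, not its own
  expect_false(isTRUE(all.equal(mean(nm$test$f1), 0, tolerance = 1e-6)))
  expect_equal(nm$test$f2,
               (sp$test$f2 - mean(sp$train$f2)) / stats::sd(sp$train$f2))
  expect_identical(nm$dropped, "konst")
})

test_that("mRMR: relevance first, redundancy penalized, deterministic", {
  set.seed(9)
  n <- 80
  y <- stats::rbinom(n, 1, 0.5)
  df <- data.frame(noise_a = stats::rnorm(n), noise_b = stats::rnorm(n),
                   oracle = y + stats::rnorm(n, 0, 0.05))
  df$oracle_copy <- df$oracle
  sel <- mrmr_select(df, y, k = 2)
  expect_identical(sel[1], "oracle")
  # exact duplicate never selected second
  expect_false(sel[2] == "oracle_copy")
  # brute-force check of the second pick's criterion
  disc <- lapply(df, resectquant:::discretize_quantiles, bins = 3)
  crit <- vapply(setdiff(names(df), "oracle"), function(f) {
    resectquant:::mutual_information(disc[[f]], y) -
      resectquant:::mutual_information(disc[[f]], disc[["oracle"]])
  }, numeric(1))
  expect_identical(sel[2], names(which.max(crit)))
  # k = all: permutation of every feature
  expect_setequal(mrmr_select(df, y, k = 4), names(df))
})

test_that("stepwise logistic keeps signal, drops noise, honours AIC", {
  keep_rate <- 0; noise_kept <- 0
  for (s in 1:25) {
    set.seed(s)
    n <- 200
    x <- stats::rnorm(n)
    y <- stats::rbinom(n, 1, stats::plogis(1.5 * x))
    df <- data.frame(y = y, signal = x,
                     n1 = stats::rnorm(n), n2 = stats::rnorm(n),
                     n3 = stats::rnorm(n), n4 = stats::rnorm(n))
    res <- stepwise_logistic(df, "y", c("signal", "n1", "n2", "n3", "n4"))
    keep_rate <- keep_rate + ("signal" %in% res$selected)
    noise_kept <- noise_kept +
      length(intersect(res$selected, c("n1", "n2", "n3", "n4")))
  }
  expect_gte(keep_rate / 25, 0.95)
  expect_lte(noise_kept / (25 * 4), 0.2)   # >= 80% of noise dropped

  # no candidate improves: intercept-only model returned
  set.seed(1)
  df0 <- data.frame(y = stats::rbinom(40, 1, 0.5), z = rep(c(1, 2), 20))
  r0 <- stepwise_logistic(df0, "y", "z")
  full <- stats::glm(y ~ z, stats::binomial(), data = df0)
  null <- stats::glm(y ~ 1, stats::binomial(), data = df0)
  expect_lte(r0$aic, stats::AIC(full) + 1e-9)
  expect_lte(r0$aic, stats::AIC(null) + 1e-9)
})

test_that("Cox fit: null coverage and tie handling", {
  covered <- vapply(1:40, function(s) {
    co <- make_cohort(cohort_spec(n_patients = 120, log_hr_per_mm = log(2),
                                  seed = 1000 + s))
    co$records$null_cov <- stats::rnorm(120)
    cf <- cox_fit(co$records, "null_cov", "OS")
    cf$ci_lower <= 1 && 1 <= cf$ci_upper
  }, logical(1))
  expect_gte(mean(covered), 0.9)

  # no events: error
  co <- make_cohort(cohort_spec(n_patients = 20, seed = 2))
  co$records$os_event <- 0L
  expect_error(cox_fit(co$records, "mean_thickness_mm"), "events")

  # Breslow and exact tie handling agree when no ties are present
  co2 <- make_cohort(cohort_spec(n_patients = 60, seed = 3))
  df <- co2$records
  f1 <- survival::coxph(survival::Surv(os_days, os_event) ~
                          mean_thickness_mm, df, ties = "breslow")
  f2 <- survival::coxph(survival::Surv(os_days, os_event) ~
                          mean_thickness_mm, df, ties = "exact")
  expect_equal(unname(stats::coef(f1)), unname(stats::coef(f2)),
               tolerance = 1e-6)
})

test_that("Kaplan-Meier and log-rank match hand computation on the toy", {
  # group A: 5 censored, 10, 15; group B: 2, 4, 6 (all events)
  toy <- data.frame(os_days = c(5, 10, 15, 2, 4, 6),
                    os_event = c(0, 1, 1, 1, 1, 1),
                    grp = c(1, 1, 1, 0, 0, 0))
  kl <- km_logrank(toy, "grp", 0.5, "OS")
  expect_equal(kl$chisq,
               hand_logrank(toy$os_days, toy$os_event, toy$grp),
               tolerance = 1e-9)
  expect_equal(kl$p, stats::pchisq(kl$chisq, 1, lower.tail = FALSE))

  # product-limit steps per stratum against the hand estimator
  sf <- summary(kl$fit)
  for (g in c(0, 1)) {
    hk <- hand_km(toy$os_days[toy$grp == g], toy$os_event[toy$grp == g])
    stratum <- if (g == 0) "group=low" else "group=high"
    idx <- sf$strata == stratum
    expect_equal(unname(sf$surv[idx]), hk$surv, tolerance = 1e-12)
    expect_equal(unname(sf$time[idx]), hk$time)
  }

  # identical strata: statistic 0, p 1
  same <- data.frame(os_days = rep(c(3, 6, 9), 2),
                     os_event = 1L, grp = rep(c(0, 1), each = 3))
  kl2 <- km_logrank(same, "grp", 0.5, "OS")
  expect_lt(kl2$chisq, 1e-10)
  expect_equal(kl2$p, 1, tolerance = 1e-6)

  # survival curve starts at 1 and never increases
  s <- kl$fit$surv
  expect_true(all(s <= 1 + 1e-12))
  expect_true(all(diff(kl$fit$surv[1:3]) <= 1e-12))

  expect_error(km_logrank(toy, "grp", 5, "OS"), "empty stratum")
})

test_that("ROC/Youden: examples, brute-force property, symmetry", {
  r <- roc_youden(c(0.1, 0.4, 0.35, 0.8), c(0, 1, 0, 1))
  expect_equal(r$auc, 1)   # 4/4 concordant pairs
  expect_gte(r$youden_threshold, 0.35)
  expect_lt(r$youden_threshold, 0.4)
  expect_equal(r$sensitivity, 1)
  expect_equal(r$specificity, 1)

  # AUC equals brute-force concordant-pair fraction (with ties)
  set.seed(21)
  for (i in 1:20) {
    n <- sample(6:50, 1)
    sc <- sample(seq(0, 1, 0.05), n, replace = TRUE)
    y <- stats::rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) next
    expect_equal(roc_youden(sc, y)$auc, brute_force_auc(sc, y),
                 tolerance = 1e-12)
    # symmetry: AUC(score) + AUC(-score) = 1
    expect_equal(roc_youden(sc, y)$auc + roc_youden(-sc, y)$auc, 1,
                 tolerance = 1e-12)
  }

  expect_error(roc_youden(c(1, 2), c(1, 1)), "classes")
})

test_that("BH adjustment: worked example and step-up properties", {
  p <- c(0.01, 0.02, 0.03, 0.04)
  expect_equal(bh_adjust(p), rep(0.04, 4))
  expect_equal(bh_adjust(p), hand_bh(p))

  set.seed(22)
  for (i in 1:10) {
    q <- stats::runif(sample(3:12, 1))
    adj <- bh_adjust(q)
    expect_equal(adj, hand_bh(q), tolerance = 1e-12)
    expect_true(all(adj >= q - 1e-15))          # never below raw
    ord <- order(q)
    expect_true(all(diff(adj[ord]) >= -1e-15))  # monotone step-up
    # significance decisions are stable under re-adjustment at any level:
    # re-running BH can only move adjusted p upward, never below raw
    expect_true(all(bh_adjust(adj) >= adj - 1e-15))
  }
  expect_equal(bh_adjust(0.03), 0.03)           # single p unchanged
})

test_that("subgroup analysis adjusts within covariate and flags windows", {
  co <- make_cohort(cohort_spec(n_patients = 240,
                                scan_delay_probs = rep(0.25, 4), seed = 31))
  co$records$max_thickness_mm <- co$records$mean_thickness_mm * 2.4 +
    stats::rnorm(240, 0, 0.5)
  sg <- subgroup_analysis(co$records,
                          c("mean_thickness_mm", "max_thickness_mm"))
  expect_equal(nrow(sg), 10)   # (All + 4 windows) x 2 covariates
  # adjusted never below raw, and All rows carry the raw p
  win <- sg$window != "All"
  expect_true(all(sg$p_adj[win] >= sg$p[win] - 1e-15))
  expect_equal(sg$p_adj[!win], sg$p[!win])
  # per-covariate family adjustment matches a direct BH computation
  for (cv in unique(sg$covariate)) {
    ix <- which(win & sg$covariate == cv)
    expect_equal(sg$p_adj[ix], hand_bh(sg$p[ix]), tolerance = 1e-12)
  }
  expect_true(all(sg$unstable == (sg$n_events < 10)))
})

test_that("combined model: null behaviour and informative synthetic cohort", {
  null_aucs <- vapply(1:20, function(s) {
    set.seed(s)
    rec <- make_dichot_cohort(n = 120, n_long = 40, seed = s)
    rec$age_years <- stats::rnorm(120, 60, 10)
    rec$kps_high <- stats::rbinom(120, 1, 0.5)
    rec$mean_thickness_mm <- stats::rnorm(120, 3, 1)
    rec <- dichotomize_survival(rec)
    sp <- split_cohort(rec, seed = s)
    cm <- combined_model(sp$train, sp$test)
    cm$combined$auc
  }, numeric(1))
  expect_lt(abs(mean(null_aucs) - 0.5), 0.1)

  # outcome driven by thickness plus one radiomics feature: the combined
  # model is competitive with each single-family model on held-out data,
  # and permuting the training labels destroys the test AUC
  res <- vapply(1:25, function(s) {
    set.seed(400 + s)
    n <- 300
    K <- 14
    th <- stats::rnorm(n, 3, 1.2)
    r1 <- stats::rnorm(n)
    long <- stats::rbinom(n, 1, stats::plogis(-1.0 * (th - 3) + 0.8 * r1))
    nz <- matrix(stats::rnorm(n * K), n, K,
                 dimnames = list(NULL, paste0("nz", 1:K)))
    rec <- data.frame(id = as.character(1:n),
                      os_days = ifelse(long == 1, 1000, 300),
                      os_event = 1L, mean_thickness_mm = th, r1 = r1, nz)
    rec <- dichotomize_survival(rec)
    sp <- split_cohort(rec, seed = s)
    specs <- list(thickness = "mean_thickness_mm",
                  radiomics = c("r1", paste0("nz", 1:K)),
                  combined = c("mean_thickness_mm", "r1",
                               paste0("nz", 1:K)))
    cm <- combined_model(sp$train, sp$test, model_specs = specs)
    perm_auc <- mean(vapply(1:3, function(j) {
      perm <- sp$train
      perm$os_long <- sample(perm$os_long)
      combined_model(perm, sp$test,
                     model_specs = specs["combined"])$combined$auc
    }, numeric(1)))
    c(cm$combined$auc >= max(cm$thickness$auc, cm$radiomics$auc) - 0.05,
      perm_auc)
  }, numeric(2))
  expect_gte(mean(res[1, ]), 0.8)
  expect_gte(mean(res[2, ] <= 0.6), 0.9)   # permuted labels: AUC collapses
})
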