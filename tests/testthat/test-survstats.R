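test_that("product-limit estimator matches the hand calculation", {
  s <- survival_sample(c(5, 10, 15), c(1, 0, 1))
  km <- km_estimate(s)
  expect_equal(km$time, c(5, 15))
  expect_equal(km$surv, c(2 / 3, 0))
  expect_equal(km$median_months, 15)
  expect_true(km$median_reached)
  # no events: S = 1 everywhere, median undefined and flagged
  km0 <- km_estimate(survival_sample(c(3, 8), c(0, 0)))
  expect_equal(km_surv_at(km0, c(1, 100)), c(1, 1))
  expect_true(is.na(km0$median_months))
  expect_false(km0$median_reached)
  # all events at distinct times: uniform 1/n steps
  kmn <- km_estimate(survival_sample(1:5, rep(1, 5)))
  expect_equal(kmn$surv, seq(0.8, 0, by = -0.2))
})

test_that("KM with no censoring equals the empirical survival function", {
  set.seed(1)
  t <- round(rexp(40, 0.1), 1) + 0.1
  km <- km_estimate(survival_sample(t, rep(1, 40)))
  ecdf_surv <- vapply(km$time, function(x) mean(t > x), numeric(1))
  expect_equal(km$surv, ecdf_surv)
})

test_that("KM, log-rank and Cox match the reference implementation on random data", {
  skip_if_not_installed("survival")
  for (k in 1:20) {
    d <- random_surv_data(n = 30 + 5 * k, beta = (k %% 3) * 0.4, seed = k)
    # Kaplan-Meier
    km <- km_estimate(survival_sample(d$time, d$event))
    sf <- survival::survfit(survival::Surv(d$time, d$event) ~ 1)
    expect_equal(km$surv, sf$surv[sf$n.event > 0], tolerance = 1e-10)
    # survfit averages times when the curve sits exactly at 0.5; compare
    # medians only away from that knife-edge
    if (!any(abs(km$surv - 0.5) < 1e-12)) {
      expect_equal(unname(summary(sf)$table["median"]), km$median_months)
    }
    # log-rank
    a <- survival_sample(d$time[d$x == 1], d$event[d$x == 1])
    b <- survival_sample(d$time[d$x == 0], d$event[d$x == 0])
    lr <- logrank_test(a, b)
    sd_ <- survival::survdiff(survival::Surv(d$time, d$event) ~ d$x)
    expect_equal(lr$chi2, sd_$chisq, tolerance = 1e-6)
    # Cox, both tie corrections, beta and se to 1e-5
    smp <- survival_sample(d$time, d$event)
    x2 <- cbind(g = d$x, z = (d$time * 7919) %% 1)  # add a continuous covariate
    for (ties in c("efron", "breslow")) {
      f <- cox_fit(x2, smp, ties = ties)
      ref <- survival::coxph(survival::Surv(d$time, d$event) ~ x2,
                             ties = ties)
      expect_equal(f$coefficients$beta, unname(coef(ref)), tolerance = 1e-5)
      expect_equal(f$coefficients$se, unname(sqrt(diag(vcov(ref)))),
                   tolerance = 1e-5)
    }
  }
})

test_that("log-rank on identical groups is exactly null", {
  s <- survival_sample(c(2, 4, 6, 9), c(1, 1, 0, 1))
  lr <- logrank_test(s, s)
  expect_equal(lr$chi2, 0)
  expect_equal(lr$p, 1)
  expect_error(logrank_test(s, survival_sample(numeric(0), integer(0))),
               "positive|nonempty")
})

test_that("Cox recovers a generated hazard ratio and flags degenerate fits", {
  d <- random_surv_data(500, beta = log(2.3), seed = 99)
  f <- cox_fit(matrix(d$x, ncol = 1), survival_sample(d$time, d$event))
  expect_true(f$converged)
  expect_true(f$coefficients$ci_lower < 2.3 && 2.3 < f$coefficients$ci_upper)
  # null covariate: HR near 1
  d0 <- random_surv_data(800, beta = 0, seed = 123)
  f0 <- cox_fit(matrix(d0$x, ncol = 1), survival_sample(d0$time, d0$event))
  expect_equal(f0$coefficients$hr, 1, tolerance = 0.25)
  # constant covariate rejected
  expect_error(cox_fit(matrix(1, nrow = 800), survival_sample(d0$time, d0$event)),
               "constant")
  # perfect separation: flagged, not silent
  tt <- c(1:10, 101:110)
  xx <- rep(c(1, 0), each = 10)
  fs <- cox_fit(matrix(xx, ncol = 1), survival_sample(tt, rep(1, 20)))
  expect_true(fs$monotone || !fs$converged)
})

test_that("ROC cutoff maximizes Youden J and matches brute force", {
  # perfectly separating feature
  r <- roc_best_cutoff(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1))
  expect_equal(r$youden_j, 1)
  expect_equal(r$auc, 1)
  expect_gt(r$threshold, 3); expect_lt(r$threshold, 10)
  # 6-point hand example against exhaustive search over all cutpoints
  v <- c(2, 5, 3, 8, 7, 4); y <- c(0, 1, 0, 1, 0, 1)
  r2 <- roc_best_cutoff(v, y)
  brute_j <- function(th) mean(v[y == 1] > th) + mean(v[y == 0] <= th) - 1
  cand <- sort(unique(v)); mids <- (cand[-1] + cand[-length(cand)]) / 2
  best <- mids[which.max(sapply(mids, brute_j))]
  expect_equal(r2$threshold, best)
  expect_equal(r2$youden_j, max(sapply(mids, brute_j)))
  expect_error(roc_best_cutoff(1:5, rep(1, 5)), "both outcome classes")
})

test_that("ROC AUC agrees with an independent implementation and is ~0.5 under independence", {
  skip_if_not_installed("pROC")
  set.seed(31)
  v <- rnorm(300); y <- rbinom(300, 1, 0.5)
  r <- roc_best_cutoff(v, y)
  ref <- pROC::roc(y, v, quiet = TRUE, direction = "<")
  expect_equal(r$auc, as.numeric(pROC::auc(ref)), tolerance = 1e-10)
  expect_equal(r$auc, 0.5, tolerance = 0.08)
  # informative feature cross-check too
  v2 <- rnorm(300) + y
  r2 <- roc_best_cutoff(v2, y)
  expect_equal(r2$auc,
               as.numeric(pROC::auc(pROC::roc(y, v2, quiet = TRUE,
                                              direction = "<"))),
               tolerance = 1e-10)
})

test_that("combined strata assign deterministically with the > cutoff rule", {
  st <- combined_strata(c(100, 200, 200.0001, 500), 200,
                        c("complete", "complete", "not_complete", NA))
  expect_equal(as.character(st),
               c("lowMTV_CMR", "lowMTV_CMR", "highMTV_nonCMR", NA))
  expect_equal(attr(st, "n_missing_response"), 1L)
  expect_equal(levels(st), c("lowMTV_CMR", "lowMTV_nonCMR",
                             "highMTV_CMR", "highMTV_nonCMR"))
})
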