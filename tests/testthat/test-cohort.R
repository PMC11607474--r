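test_that("Weibull PH sampler has the right scale and PH behavior", {
  set.seed(2)
  # shape 1, scale 50, no censoring: exponential with mean 50
  d <- sample_survival(rep(0, 1e5), shape = 1, scale = 50,
                       censor_months = Inf)
  expect_equal(mean(d$time_months), 50, tolerance = 0.02)
  expect_true(all(d$event == 1))
  # lp = ln 2 halves the median relative to lp = 0 (shape 1)
  d0 <- sample_survival(rep(0, 1e5), 1, 50, Inf)
  d1 <- sample_survival(rep(log(2), 1e5), 1, 50, Inf)
  expect_equal(median(d1$time_months) / median(d0$time_months), 0.5,
               tolerance = 0.03)
  # degenerate censoring at 0
  dz <- sample_survival(0, 1, 50, censor_months = 0)
  expect_equal(dz$time_months, 0)
  expect_equal(dz$event, 0L)
  expect_error(sample_survival(0, -1, 50, 10), "shape")
})

test_that("cohort generation is reproducible and structurally consistent", {
  cfg <- cohort_sim_config(n_patients = 150, seed = 21)
  co <- generate_cohort(cfg)
  expect_identical(co, generate_cohort(cfg))
  expect_equal(nrow(co), 150)
  expect_true(all(co$n_lesions >= 2))           # at least two lesions each
  expect_true(all(co$pfs_months <= co$os_months + 1e-12))
  expect_true(all(co$os_event <= co$pfs_event)) # death implies progression event
  expect_true(all(co$deauville[co$response == "complete"] <= 3))
  expect_true(all(co$deauville[co$response == "not_complete"] >= 4))
  expect_true(all(co$suv_max_lbm < co$suv_max_bw))
  expect_equal(co$dmax_bsa, co$dmax_cm / co$bsa_m2)
  # response label consistent with the Lugano mapping of its Deauville score
  expect_equal(co$response,
               mapply(lugano_response, co$deauville, co$new_lesions))
  # invalid configs rejected
  expect_error(cohort_sim_config(n_patients = 1), "n_patients")
  expect_error(cohort_sim_config(lesion_lambda = -1), "lambda")
  expect_error(cohort_sim_config(censor_months = 0), "censor")
  expect_error(cohort_sim_config(
    baseline_weibull = c(shape = 1.2, scale_pfs = 80, scale_os = 80)),
    "dominates")
})

test_that("simulated marginals sit in the published clinical ranges", {
  co <- generate_cohort(cohort_sim_config(n_patients = 600, seed = 4))
  expect_true(all(co$suv_max_bw >= 3.5 & co$suv_max_bw <= 14.5))
  expect_true(all(co$mtv_cm3 >= 2 & co$mtv_cm3 <= 4000))
  expect_equal(mean(co$mtv_cm3), 491, tolerance = 0.15)
  expect_equal(median(co$suv_max_bw), 9, tolerance = 0.1)
  expect_equal(mean(co$dmax_cm), 54.6, tolerance = 0.1)
  expect_equal(mean(co$dmax_bsa), 29.5, tolerance = 0.12)
  expect_equal(mean(co$response == "not_complete"), 0.30, tolerance = 0.25)
  # older / Ki-67-high patients miss complete response more often
  noncr <- co$response == "not_complete"
  expect_gt(mean(co$age_years[noncr]), mean(co$age_years[!noncr]))
  expect_gt(mean(co$ki67_high[noncr]), mean(co$ki67_high[!noncr]))
})

test_that("under a null hazard the Cox p-values are approximately uniform", {
  null_haz <- list(pfs_beta_mtv = 0, pfs_beta_response = 0,
                   os_beta_dmaxbsa = 0)
  set.seed(17)
  seeds <- sample.int(.Machine$integer.max, 200)
  pvals <- vapply(seeds, function(s) {
    co <- generate_cohort(cohort_sim_config(n_patients = 120,
                                            hazard = null_haz, seed = s))
    smp <- survival_sample(co$pfs_months, co$pfs_event)
    cox_fit(matrix(as.numeric(co$mtv_cm3 > 358), ncol = 1),
            smp)$coefficients$p
  }, numeric(1))
  ks <- suppressWarnings(ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("the smallest legal cohort flows through every downstream stage", {
  co <- generate_cohort(cohort_sim_config(n_patients = 2, seed = 1))
  expect_equal(nrow(co), 2)
  km <- km_estimate(survival_sample(co$pfs_months, pmax(co$pfs_event, 1)))
  expect_s3_class(km, "km_curve")
  expect_equal(dmax_bsa(co$dmax_cm, co$bsa_m2), co$dmax_bsa)
  st <- combined_strata(co$mtv_cm3, 358, co$response)
  expect_length(st, 2)
})

test_that("cohort CSV roundtrip preserves the table and the seed", {
  co <- generate_cohort(cohort_sim_config(n_patients = 25, seed = 12))
  path <- file.path(withr::local_tempdir(), "cohort.csv")
  write_cohort_csv(co, path)
  expect_true(any(grepl("seed: 12", readLines(path, n = 1))))
  back <- read_cohort_csv(path)
  expect_equal(back$mtv_cm3, co$mtv_cm3, tolerance = 1e-8)
  expect_equal(back$pfs_event, co$pfs_event)
  expect_equal(nrow(back), 25)
})
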