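small_cohort <- function(seed, n = 25, h0 = 0.08) {
  cfg <- sim_config(seed = seed, n_patients = n, h0 = h0)
  generate_cohort(cfg)$records
}

test_that("the inclusion filter drops follow-up of 90 days or less", {
  recs <- tibble::tibble(
    patient_id = c("a", "b", "c", "d"),
    followup_years = c(0.3, 0.1, 91 / 365.25, 90 / 365.25)
  )
  kept <- apply_inclusion_filter(recs)
  expect_equal(kept$patient_id, c("a", "c")) # exactly 90 days is excluded
  expect_equal(attr(kept, "n_removed"), 2)
  empty <- apply_inclusion_filter(recs[0, ])
  expect_equal(nrow(empty), 0)
})

test_that("counting-process expansion splits at the revascularization time", {
  recs <- tibble::tibble(
    patient_id = c("a", "b", "c"),
    age = 60, sex = "male",
    followup_years = c(5, 8, 6),
    death = c(1L, 0L, 0L),
    revasc_years = c(NA, 2, 6),
    cfc_normal = 0.7, cfc_mild = 0.1, cfc_severe = 0.15, scar = 0.05,
    prior_revasc = 0L
  )
  expect_warning(rows <- expand_time_dependent(recs), "single interval")
  a <- dplyr::filter(rows, patient_id == "a")
  expect_equal(nrow(a), 1)
  expect_equal(c(a$tstart, a$tstop, a$event, a$revasc), c(0, 5, 1, 0))
  b <- dplyr::filter(rows, patient_id == "b")
  expect_equal(nrow(b), 2)
  expect_equal(b$tstart, c(0, 2))
  expect_equal(b$tstop, c(2, 8))
  expect_equal(b$revasc, c(0L, 1L))
  expect_equal(b$event, c(0L, 0L))
  # revasc at end of follow-up falls back to a single row
  cc <- dplyr::filter(rows, patient_id == "c")
  expect_equal(nrow(cc), 1)
  expect_equal(cc$revasc, 0L)
  expect_true(all(rows$severe_ind == 1L))
})

test_that("partial likelihood and score match direct risk-set sums", {
  covs <- c("cfc_mild", "cfc_severe", "scar", "age", "sex_male", "revasc",
            "revasc_x_severe")
  for (seed in c(101, 102, 103)) {
    rows <- expand_time_dependent(small_cohort(seed, n = 28))
    rows$revasc_x_severe <- rows$revasc * rows$severe_ind
    use <- covs[vapply(covs, function(v) stats::var(rows[[v]]) > 0,
                       logical(1))]
    beta <- stats::rnorm(length(use), 0, 0.4)
    fml <- stats::as.formula(paste(
      "survival::Surv(tstart, tstop, event) ~", paste(use, collapse = "+")))
    ref <- survival::coxph(fml, data = as.data.frame(rows), ties = "efron",
                           init = beta,
                           control = survival::coxph.control(iter.max = 0))
    mine <- cox_partial_loglik(beta, rows, use)
    expect_equal(mine$loglik, ref$loglik[1], tolerance = 1e-10)
    expect_equal(unname(mine$score),
                 unname(colSums(residuals(ref, type = "score"))),
                 tolerance = 1e-8)
  }
})

test_that("fitted coefficients maximise the in-repo partial likelihood", {
  recs <- small_cohort(104, n = 30)
  rows <- expand_time_dependent(apply_inclusion_filter(recs))
  covs <- c("cfc_mild", "cfc_severe", "age")
  fit <- fit_cox(rows, covariates = covs)
  at_hat <- cox_partial_loglik(fit$coefficients, rows, covs)
  expect_equal(at_hat$loglik, fit$loglik, tolerance = 1e-8)
  expect_lt(max(abs(at_hat$score)), 1e-4)
})

test_that("the partial likelihood is invariant to cohort duplication", {
  recs <- small_cohort(105, n = 30)
  rows <- expand_time_dependent(recs)
  covs <- c("cfc_mild", "cfc_severe", "age")
  # duplication creates exact event-time ties across copies, so the
  # invariance holds under the Breslow tie approximation
  f1 <- fit_cox(rows, covariates = covs, ties = "breslow")
  dup <- dplyr::mutate(recs, patient_id = paste0(patient_id, "-copy"))
  f2 <- fit_cox(expand_time_dependent(dplyr::bind_rows(recs, dup)),
                covariates = covs, ties = "breslow")
  expect_equal(unname(f1$coefficients), unname(f2$coefficients),
               tolerance = 1e-6)
})

test_that("fit refuses degenerate inputs", {
  recs <- small_cohort(106, n = 20)
  recs$death <- 0L
  expect_error(fit_cox(expand_time_dependent(recs)), "2 events")
  recs2 <- small_cohort(106, n = 20)
  recs2$cfc_mild <- 0.2
  expect_error(fit_cox(expand_time_dependent(recs2),
                       covariates = c("cfc_mild", "age")),
               "constant covariate")
})

test_that("prediction reduces to the baseline at zero covariates", {
  fit <- structure(list(
    coefficients = c(cfc_severe = 1.5, age = 0.03),
    covariates = c("cfc_severe", "age"),
    baseline = tibble::tibble(time = c(1, 4, 9), hazard = c(0.01, 0.05, 0.2))
  ), class = "cfc_cox_fit")
  x0 <- tibble::tibble(cfc_mild = 0, cfc_severe = 0, scar = 0, age = 0,
                       sex_male = 0)
  p <- predict_survival(fit, x0, horizon = 9)
  expect_equal(p$probability, exp(-0.2))
  expect_equal(predict_survival(fit, x0, horizon = 0.5)$probability, 1)
  # step function + last value carried forward, flagged
  p20 <- predict_survival(fit, x0, horizon = 20)
  expect_equal(p20$probability, exp(-0.2))
  expect_true(p20$extrapolated)
  # S(t) non-increasing in horizon
  probs <- vapply(c(0.5, 1, 2, 4, 8, 9, 12),
                  function(h) predict_survival(fit, x0, h)$probability,
                  numeric(1))
  expect_true(all(diff(probs) <= 0))
  # larger severe burden strictly lowers survival under a positive effect
  xs <- tibble::tibble(cfc_mild = 0, cfc_severe = c(0.1, 0.4), scar = 0,
                       age = 0, sex_male = 0)
  ps <- predict_survival(fit, xs, horizon = 9)
  expect_lt(ps$probability[2], ps$probability[1])
})

test_that("scaled covariates with inversely scaled coefficients predict identically", {
  fit1 <- structure(list(
    coefficients = c(cfc_severe = 1.5, age = 0.03),
    covariates = c("cfc_severe", "age"),
    baseline = tibble::tibble(time = c(1, 9), hazard = c(0.02, 0.15))
  ), class = "cfc_cox_fit")
  fit2 <- fit1
  fit2$coefficients <- fit1$coefficients / 2
  x <- tibble::tibble(cfc_mild = 0, cfc_severe = 0.3, scar = 0, age = 50,
                      sex_male = 0)
  x2 <- dplyr::mutate(x, cfc_severe = cfc_severe * 2, age = age * 2)
  expect_equal(predict_survival(fit1, x, 9)$probability,
               predict_survival(fit2, x2, 9)$probability)
})

test_that("mortality contrast is null when revascularization has no effect", {
  fit <- structure(list(
    coefficients = c(cfc_mild = 0.5, cfc_severe = 1.5, scar = 1, age = 0.02,
                     sex_male = 0.2, revasc = 0, revasc_x_severe = 0),
    covariates = c("cfc_mild", "cfc_severe", "scar", "age", "sex_male",
                   "revasc", "revasc_x_severe"),
    baseline = tibble::tibble(time = c(2, 10), hazard = c(0.05, 0.2))
  ), class = "cfc_cox_fit")
  recs <- tibble::tibble(
    patient_id = c("a", "b"), age = c(60, 70), sex = c("male", "female"),
    cfc_normal = c(0.9, 0.5), cfc_mild = c(0.1, 0.2),
    cfc_severe = c(0, 0.25), scar = c(0, 0.05)
  )
  ct <- cohort_mortality_contrast(fit, recs, horizon = 10)
  wide <- tidyr::pivot_wider(ct, id_cols = "stratum",
                             names_from = "pathway",
                             values_from = "mean_mortality")
  expect_equal(wide$no_revasc, wide$revasc_at_t0)
  ct0 <- cohort_mortality_contrast(fit, recs, horizon = 1)
  expect_true(all(ct0$mean_mortality == 0)) # before the first event time
})
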