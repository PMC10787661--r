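test_that("generation is fully determined by the seed", {
  cfg <- sim_config(seed = 61, n_patients = 20)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$records, b$records)
  expect_identical(a$truth, b$truth)
  c2 <- generate_cohort(sim_config(seed = 62, n_patients = 20))
  expect_false(identical(a$records$followup_years,
                         c2$records$followup_years))
})

test_that("defect extents round-trip through the classifier", {
  cfg <- sim_config(seed = 63)
  for (cls in c("MILD", "MODERATE", "SEVERE", "STEAL", "SCAR")) {
    set.seed(cfc_rank(cls) + 100)
    g <- generate_study(cfg, "rt", tibble::tibble(
      territory = "LCx", class = cls, extent = 0.12))
    meas <- cfc_covariates(summarize_map(build_cfc_map(g$study)))
    cols <- c("cfc_normal", "cfc_mild", "cfc_severe", "scar")
    expect_equal(unlist(meas[, cols]), unlist(g$true_fractions[, cols]),
                 tolerance = 1e-12)
    grp <- switch(cls, MILD = "cfc_mild", SCAR = "scar", "cfc_severe")
    # defect + its one-pixel rim: extent recovered within the rim allowance
    target_px <- round(0.12 * 1344)
    expect_gte(meas[[grp]], target_px / 1344 - 1e-12)
    expect_lt(abs(meas[[grp]] - target_px / 1344), 150 / 1344)
  }
})

test_that("a defect-free study classifies as normal CFC", {
  cfg <- sim_config(seed = 64)
  set.seed(64)
  g <- generate_study(cfg, "bg")
  m <- build_cfc_map(g$study)
  expect_gte(mean(m$cfc_class %in% c("EXCELLENT", "ADEQUATE")), 0.99)
})

test_that("defect regions are contiguous within their territory", {
  cfg <- sim_config(seed = 65)
  set.seed(65)
  g <- generate_study(cfg, "ct", tibble::tibble(
    territory = "RCA", class = "SEVERE", extent = 0.1))
  lay <- polar_layout()
  sev <- which(g$true_class == "SEVERE")
  expect_true(all(lay$territory[sev] == "RCA"))
  # breadth-first connectivity: every severe pixel reachable from the first
  key <- paste(lay$ring, lay$sector)
  sevset <- lay[sev, ]
  reached <- 1L
  frontier <- 1L
  adj <- function(i, j) {
    (abs(sevset$ring[i] - sevset$ring[j]) == 1 &
       sevset$sector[i] == sevset$sector[j]) |
      (sevset$ring[i] == sevset$ring[j] &
         (abs(sevset$sector[i] - sevset$sector[j]) %in% c(1, 63)))
  }
  while (length(frontier)) {
    nxt <- setdiff(which(vapply(seq_len(nrow(sevset)), function(j)
      any(adj(frontier, j)), logical(1))), reached)
    reached <- c(reached, nxt)
    frontier <- nxt
  }
  expect_equal(sort(reached), seq_len(nrow(sevset)))

  # oversized defects spill contiguously beyond their territory
  set.seed(66)
  g2 <- generate_study(cfg, "big", tibble::tibble(
    territory = "RCA", class = "SEVERE", extent = 0.45))
  expect_equal(sum(g2$true_class == "SEVERE"), round(0.45 * 1344))
  expect_error(generate_study(cfg, "huge", tibble::tibble(
    territory = "RCA", class = "SEVERE", extent = 1.2)),
    "pixel count")
})

test_that("null-hazard survival matches the exponential closed form", {
  cfg <- sim_config(seed = 66, n_patients = 5000,
                    beta_mild = 0, beta_severe = 0, beta_scar = 0,
                    beta_age = 0, beta_sex = 0, beta_revasc = 0,
                    beta_interaction = 0, h0 = 0.03)
  co <- generate_cohort(cfg)
  km <- survival::survfit(
    survival::Surv(followup_years, death) ~ 1,
    data = co$records)
  s10 <- summary(km, times = 10)$surv
  expect_equal(s10, exp(-0.3), tolerance = 0.02)
  expect_true(all(co$truth$true_s10_no_revasc == exp(-0.3)))
})

test_that("piecewise hazard follows the two-piece exponential closed form", {
  # revascularization for everyone at t = 2 with hazard ratio exp(-1)
  cfg <- sim_config(seed = 67, n_patients = 20000,
                    beta_mild = 0, beta_severe = 0, beta_scar = 0,
                    beta_age = 0, beta_sex = 0,
                    beta_revasc = -1, beta_interaction = 0,
                    h0 = 0.1,
                    revasc_intercept = 50, revasc_slope = 0,
                    revasc_time_range = c(2, 2),
                    admin_censor_years = 1e6,
                    dropout_range = c(1e6, 1e6 + 1))
  co <- generate_cohort(cfg)
  t_ev <- co$truth$event_time
  # S(t) = exp(-h1 t) for t < r; exp(-h1 r - h1 e^{-1} (t - r)) after
  s_emp <- function(t) mean(t_ev > t)
  expect_equal(s_emp(1), exp(-0.1), tolerance = 0.01)
  expect_equal(s_emp(2), exp(-0.2), tolerance = 0.01)
  expect_equal(s_emp(6), exp(-0.2 - 0.1 * exp(-1) * 4), tolerance = 0.01)
})

test_that("protective interaction raises survival only for revascularized severe", {
  cfg <- sim_config(seed = 68, n_patients = 6000)
  co <- generate_cohort(cfg)
  tr <- co$truth
  rec <- co$records
  sev <- rec$cfc_severe > 0
  rv <- !is.na(rec$revasc_years)
  km10 <- function(sel) {
    f <- survival::survfit(survival::Surv(followup_years, death) ~ 1,
                           data = rec[sel, ])
    summary(f, times = 10)$surv
  }
  expect_gt(km10(sev & rv), km10(sev & !rv))
})

test_that("paired archetypes shape the post-revascularization maps", {
  cfg <- sim_config(seed = 69, n_patients = 40)
  pc <- generate_paired_cohort(cfg)
  expect_equal(names(pc$pre), names(pc$post))
  for (i in seq_along(pc$pre)) {
    arch <- pc$truth$archetype[i]
    pre_s <- cfc_covariates(summarize_map(build_cfc_map(pc$pre[[i]])))
    post_s <- cfc_covariates(summarize_map(build_cfc_map(pc$post[[i]])))
    if (arch == "complete") {
      expect_equal(post_s$cfc_severe, 0)
    } else if (arch == "failed") {
      d <- ks_compare(severity_histogram(build_cfc_map(pc$pre[[i]])),
                      severity_histogram(build_cfc_map(pc$post[[i]])))
      expect_equal(d$statistic, 0)
    } else if (arch == "partial") {
      expect_equal(post_s$cfc_severe, pre_s$cfc_severe / 2,
                   tolerance = 2 / 1344 / max(pre_s$cfc_severe, 1e-9))
    } else if (arch == "harmed") {
      expect_gt(post_s$cfc_mild + post_s$cfc_severe,
                pre_s$cfc_mild + pre_s$cfc_severe)
    }
  }
})
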