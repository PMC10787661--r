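#' Simulation configuration
#'
#' Collects every knob of the synthetic cohort generator: polar-map layout,
#' defect-archetype mixture, perfusion sampling, the proportional-hazards
#' parameters of the survival process, the confounded revascularization
#' assignment rule and censoring. The seed fully determines all output.
#'
#' Default hazard parameters encode the qualitative structure of a referral
#' CAD cohort: baseline all-cause hazard 0.03/yr; strong severe-CFC effect
#' (`beta_severe` = 2 per unit LV fraction), weaker mild and scar effects;
#' a mildly harmful revascularization main effect (procedures on
#' near-normal hearts carry risk) and a protective interaction with severe
#' involvement so the net severe-stratum hazard ratio is
#' `exp(0.25 - 0.9) = 0.52`. Revascularization probability is logistic in
#' the severe fraction (confounding by indication). Administrative
#' censoring is at 12 years with additional uniform drop-out.
#'
#' @param seed Integer seed.
#' @param n_patients Cohort size.
#' @param n_rings,n_sectors Polar-map layout.
#' @param archetype_probs Named probabilities for the per-patient defect
#'   archetype (`none`, `MILD`, `MODERATE`, `SEVERE`, `STEAL`, `SCAR`).
#' @param extent_range Uniform range of the defect extent (fraction of LV).
#' @param mild_surround_max Defect patients additionally carry a diffuse
#'   mild component drawn uniform on `[0, mild_surround_max]`.
#' @param diffuse_scale Global stress multiplier (1 = none).
#' @param microvascular Replace the background with diffusely mild CFC and a
#'   preserved subendocardial ratio.
#' @param subendo_profile `"preserved"` (ratio ~ 1) or `"reduced"`
#'   (ratio ~ 0.8, the diffuse-CAD pattern).
#' @param h0 Baseline hazard per year.
#' @param beta_mild,beta_severe,beta_scar,beta_age,beta_sex,beta_revasc,beta_interaction
#'   Log-hazard coefficients (age is centred at 65 years in the generating
#'   linear predictor; sex coefficient applies to males).
#' @param revasc_intercept,revasc_slope Logistic revascularization
#'   assignment: `plogis(intercept + slope * cfc_severe)`.
#' @param revasc_time_range Uniform range of revascularization times
#'   (years).
#' @param admin_censor_years Administrative censoring horizon.
#' @param dropout_range Uniform drop-out time range (values above the
#'   administrative horizon mean no drop-out).
#' @return List of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_patients = 2000L,
                       n_rings = 21L, n_sectors = 64L,
                       archetype_probs = c(none = 0.38, MILD = 0.24,
                                           MODERATE = 0.15, SEVERE = 0.13,
                                           STEAL = 0.04, SCAR = 0.06),
                       extent_range = c(0.05, 0.45),
                       mild_surround_max = 0.2,
                       diffuse_scale = 1,
                       microvascular = FALSE,
                       subendo_profile = c("preserved", "reduced"),
                       h0 = 0.03,
                       beta_mild = 0.8, beta_severe = 2.0, beta_scar = 1.5,
                       beta_age = 0.04, beta_sex = 0.3,
                       beta_revasc = 0.25, beta_interaction = -0.9,
                       revasc_intercept = -2.2, revasc_slope = 6,
                       revasc_time_range = c(0.1, 2),
                       admin_censor_years = 12,
                       dropout_range = c(0.5, 30)) {
  subendo_profile <- match.arg(subendo_profile)
  stopifnot(h0 > 0, abs(sum(archetype_probs) - 1) < 1e-9,
            all(extent_range >= 0 & extent_range <= 1))
  structure(as.list(environment()), class = "sim_config")
}

# (CFR, stress) sampling boxes sitting strictly inside each class's decision
# region under the worst-rank rule; rest = stress / CFR.
.class_boxes <- list(
  EXCELLENT = list(cfr = c(3.00, 3.80), stress = c(2.30, 3.20)),
  ADEQUATE  = list(cfr = c(2.42, 2.88), stress = c(1.85, 2.15)),
  MILD      = list(cfr = c(1.65, 2.35), stress = c(1.12, 1.80)),
  MODERATE  = list(cfr = c(1.30, 1.58), stress = c(0.86, 1.07)),
  SEVERE    = list(cfr = c(1.02, 1.26), stress = c(0.34, 0.82)),
  STEAL     = list(cfr = c(0.55, 0.95), stress = c(0.34, 0.78))
)

draw_class_perfusion <- function(class, n) {
  if (class == "SCAR") {
    v <- stats::runif(n, 0.12, 0.28)
    return(tibble::tibble(rest = v, stress = v))
  }
  box <- .class_boxes[[class]]
  cfr <- stats::runif(n, box$cfr[1], box$cfr[2])
  stress <- stats::runif(n, box$stress[1], box$stress[2])
  tibble::tibble(rest = stress / cfr, stress = stress)
}

milder_class <- function(class) {
  r <- cfc_rank(class)
  cfc_levels[max(r, 1L)] # one rank milder; EXCELLENT stays
}

# contiguous pixel set grown breadth-first from a random seed pixel within
# one territory, with sector wraparound; defects larger than the territory
# spill contiguously into the neighbouring territories
grow_defect <- function(layout, territory, n_target, n_sectors) {
  terr_idx <- which(layout$territory == territory)
  if (n_target > nrow(layout)) {
    stop("defect extent exceeds the LV pixel count", call. = FALSE)
  }
  terr_set <- logical(nrow(layout))
  terr_set[terr_idx] <- TRUE
  if (n_target > length(terr_idx)) terr_set[] <- TRUE
  key <- layout$ring * n_sectors + layout$sector
  pos <- integer(max(key) + 1L); pos[key + 1L] <- seq_len(nrow(layout))
  seed_px <- sample(terr_idx, 1)
  chosen <- integer(0)
  frontier <- seed_px
  in_set <- logical(nrow(layout))
  in_set[seed_px] <- TRUE
  while (length(chosen) < n_target && length(frontier)) {
    take <- min(n_target - length(chosen), length(frontier))
    chosen <- c(chosen, frontier[seq_len(take)])
    nxt <- integer(0)
    for (p in frontier[seq_len(take)]) {
      r <- layout$ring[p]; s <- layout$sector[p]
      nb_key <- c(
        if (r > 0) (r - 1L) * n_sectors + s,
        if (r < max(layout$ring)) (r + 1L) * n_sectors + s,
        r * n_sectors + (s + 1L) %% n_sectors,
        r * n_sectors + (s - 1L) %% n_sectors
      )
      for (q in pos[nb_key + 1L]) {
        if (terr_set[q] && !in_set[q]) {
          in_set[q] <- TRUE
          nxt <- c(nxt, q)
        }
      }
    }
    frontier <- nxt
  }
  chosen
}

rim_pixels <- function(layout, defect_idx, n_sectors) {
  in_def <- logical(nrow(layout))
  in_def[defect_idx] <- TRUE
  key <- layout$ring * n_sectors + layout$sector
  pos <- integer(max(key) + 1L); pos[key + 1L] <- seq_len(nrow(layout))
  rim <- integer(0)
  for (p in defect_idx) {
    r <- layout$ring[p]; s <- layout$sector[p]
    nb_key <- c(
      if (r > 0) (r - 1L) * n_sectors + s,
      if (r < max(layout$ring)) (r + 1L) * n_sectors + s,
      r * n_sectors + (s + 1L) %% n_sectors,
      r * n_sectors + (s - 1L) %% n_sectors
    )
    for (q in pos[nb_key + 1L]) if (!in_def[q]) rim <- c(rim, q)
  }
  unique(rim)
}

#' Generate one synthetic perfusion study
#'
#' Background pixels are drawn inside the EXCELLENT/ADEQUATE perfusion
#' boxes (or the MILD box under the microvascular flag); each requested
#' defect is a contiguous breadth-first-grown pixel region inside its
#' artery territory with (rest, stress) drawn inside the target class's
#' decision box and a one-pixel rim drawn from the next-milder class.
#' Subendocardial/subepicardial stress layers follow the configured
#' transmural profile. RNG state is taken as-is; seed at the caller.
#'
#' @param config A [sim_config()].
#' @param patient_id Identifier for the study.
#' @param defects Tibble with columns `territory`, `class`, `extent`
#'   (fraction of LV); `NULL` for none.
#' @return List: `study` (perfusion tibble with subendo/subepi layers),
#'   `true_class` (per-pixel intended labels), `true_fractions` (one-row
#'   tibble of intended grouped fractions, rim included).
#' @export
generate_study <- function(config, patient_id = "sim-1", defects = NULL) {
  layout <- polar_layout(config$n_rings, config$n_sectors)
  n_px <- nrow(layout)
  bg_class <- if (config$microvascular) "MILD" else NA
  lab <- character(n_px)
  if (is.null(bg_class) || is.na(bg_class)) {
    lab[] <- sample(c("EXCELLENT", "ADEQUATE"), n_px, replace = TRUE,
                    prob = c(0.8, 0.2))
  } else {
    lab[] <- bg_class
  }
  if (!is.null(defects) && nrow(defects)) {
    for (i in seq_len(nrow(defects))) {
      n_target <- round(defects$extent[i] * n_px)
      if (n_target < 1) next
      idx <- grow_defect(layout, defects$territory[i], n_target,
                         config$n_sectors)
      lab[idx] <- defects$class[i]
      rim <- rim_pixels(layout, idx, config$n_sectors)
      rim <- rim[lab[rim] %in% c("EXCELLENT", "ADEQUATE")]
      lab[rim] <- milder_class(defects$class[i])
    }
  }
  perf <- tibble::tibble(rest = numeric(n_px), stress = numeric(n_px))
  for (cl in unique(lab)) {
    sel <- lab == cl
    perf[sel, ] <- draw_class_perfusion(cl, sum(sel))
  }
  perf$stress <- perf$stress * config$diffuse_scale
  ratio_target <- if (config$subendo_profile == "preserved") 1.0 else 0.8
  subepi <- perf$stress * 1.05
  subendo <- subepi * stats::rnorm(n_px, ratio_target, 0.02)
  study <- dplyr::bind_cols(
    tibble::tibble(patient_id = patient_id),
    layout,
    perf,
    tibble::tibble(subendo_stress = pmax(subendo, 0),
                   subepi_stress = subepi)
  )
  tf <- table(factor(lab, levels = cfc_levels)) / n_px
  true_fractions <- tibble::tibble(
    patient_id = patient_id,
    cfc_normal = sum(tf[c("EXCELLENT", "ADEQUATE")]),
    cfc_mild = tf[["MILD"]],
    cfc_severe = sum(tf[c("MODERATE", "SEVERE", "STEAL")]),
    scar = tf[["SCAR"]]
  )
  list(study = study, true_class = lab, true_fractions = true_fractions)
}

draw_archetypes <- function(config, n) {
  arche <- sample(names(config$archetype_probs), n, replace = TRUE,
                  prob = config$archetype_probs)
  extent <- stats::runif(n, config$extent_range[1], config$extent_range[2])
  extent[arche == "none"] <- 0
  mild_extra <- ifelse(
    arche %in% c("MODERATE", "SEVERE", "STEAL", "SCAR"),
    stats::runif(n, 0, config$mild_surround_max), 0
  )
  tibble::tibble(
    archetype = arche,
    extent = extent,
    mild_extra = mild_extra,
    cfc_mild = ifelse(arche == "MILD", extent, 0) + mild_extra,
    cfc_severe = ifelse(arche %in% c("MODERATE", "SEVERE", "STEAL"),
                        extent, 0),
    scar = ifelse(arche == "SCAR", extent, 0)
  ) |>
    dplyr::mutate(cfc_normal = 1 - .data$cfc_mild - .data$cfc_severe -
                    .data$scar)
}

#' Generate survival outcomes from covariate truths
#'
#' Event times follow a piecewise-exponential proportional-hazards process:
#' rate `h0 * exp(lp)` before revascularization and
#' `h0 * exp(lp + beta_revasc + beta_interaction * severe_ind)` after, with
#' the linear predictor built from the true CFC fractions, centred age and
#' sex. Revascularization is assigned with probability logistic in the
#' severe fraction (confounding by indication) at a uniform random time,
#' and takes place only if the patient is still under observation then.
#' Censoring is the minimum of the administrative horizon and a uniform
#' drop-out time. RNG state is taken as-is; seed at the caller.
#'
#' @param config A [sim_config()].
#' @param truths Tibble with one row per patient: `patient_id`,
#'   `cfc_normal`, `cfc_mild`, `cfc_severe`, `scar`, `age`, `sex`.
#' @return List: `records` (cohort tibble as in [read_cohort()]) and
#'   `truth` (linear predictor, true 10-year survival under both pathways,
#'   uncensored event time, assigned revascularization time).
#' @export
generate_survival <- function(config, truths) {
  n <- nrow(truths)
  sev_ind <- as.integer(truths$cfc_severe > 0)
  lp <- config$beta_mild * truths$cfc_mild +
    config$beta_severe * truths$cfc_severe +
    config$beta_scar * truths$scar +
    config$beta_age * (truths$age - 65) +
    config$beta_sex * as.integer(truths$sex == "male")
  h1 <- config$h0 * exp(lp)
  h2 <- h1 * exp(config$beta_revasc + config$beta_interaction * sev_ind)
  p_rv <- stats::plogis(config$revasc_intercept +
                          config$revasc_slope * truths$cfc_severe)
  assigned_rv <- stats::runif(n) < p_rv
  r_time <- stats::runif(n, config$revasc_time_range[1],
                         config$revasc_time_range[2])
  r_time[!assigned_rv] <- Inf
  # inverse-CDF draw from the two-piece exponential cumulative hazard
  e <- stats::rexp(n)
  event_time <- ifelse(e < h1 * r_time, e / h1,
                       r_time + (e - h1 * r_time) / h2)
  censor <- pmin(config$admin_censor_years,
                 stats::runif(n, config$dropout_range[1],
                              config$dropout_range[2]))
  followup <- pmin(event_time, censor)
  death <- as.integer(event_time <= censor)
  revasc_obs <- is.finite(r_time) & r_time < followup
  records <- tibble::tibble(
    patient_id = truths$patient_id,
    age = truths$age,
    sex = truths$sex,
    followup_years = followup,
    death = death,
    revasc_years = ifelse(revasc_obs, r_time, NA_real_),
    cfc_normal = truths$cfc_normal,
    cfc_mild = truths$cfc_mild,
    cfc_severe = truths$cfc_severe,
    scar = truths$scar,
    prior_revasc = 0L
  )
  truth <- tibble::tibble(
    patient_id = truths$patient_id,
    lp = lp,
    true_s10_no_revasc = exp(-10 * h1),
    true_s10_revasc_t0 = exp(-10 * h1 *
                               exp(config$beta_revasc +
                                     config$beta_interaction * sev_ind)),
    assigned_revasc_time = r_time,
    event_time = event_time
  )
  list(records = records, truth = truth)
}

#' Generate a full synthetic cohort
#'
#' Draws per-patient defect archetypes, ages and sexes, optionally renders
#' full pixel-level perfusion studies (in which case the survival covariates
#' are the fractions measured by [build_cfc_map()] + [summarize_map()],
#' closing the generator/classifier loop), and simulates survival outcomes.
#' With `maps = FALSE` the true fractions feed the hazard directly, which is
#' the fast path used for repeated parameter-recovery studies.
#'
#' @param config A [sim_config()].
#' @param maps Render pixel-level studies?
#' @return List: `records`, `truth` (archetype and survival truths),
#'   and `studies` (named list of perfusion tibbles) when `maps = TRUE`.
#' @export
generate_cohort <- function(config, maps = FALSE) {
  set.seed(config$seed)
  n <- config$n_patients
  arch <- draw_archetypes(config, n)
  demo <- tibble::tibble(
    patient_id = sprintf("P%05d", seq_len(n)),
    age = pmin(pmax(stats::rnorm(n, 65, 10), 30), 90),
    sex = ifelse(stats::runif(n) < 0.75, "male", "female")
  )
  truths <- dplyr::bind_cols(demo, arch)
  studies <- NULL
  if (maps) {
    studies <- vector("list", n)
    terrs <- c("LAD", "LCx", "RCA")
    for (i in seq_len(n)) {
      defects <- NULL
      if (arch$archetype[i] != "none") {
        defects <- tibble::tibble(
          territory = sample(terrs, 1),
          class = arch$archetype[i],
          extent = arch$extent[i]
        )
        if (arch$mild_extra[i] > 0) {
          defects <- dplyr::bind_rows(defects, tibble::tibble(
            territory = sample(terrs, 1),
            class = "MILD",
            extent = arch$mild_extra[i]
          ))
        }
      }
      g <- generate_study(config, demo$patient_id[i], defects)
      studies[[i]] <- g$study
      meas <- cfc_covariates(summarize_map(build_cfc_map(g$study)))
      truths[i, c("cfc_normal", "cfc_mild", "cfc_severe", "scar")] <-
        meas[, c("cfc_normal", "cfc_mild", "cfc_severe", "scar")]
    }
    names(studies) <- demo$patient_id
  }
  surv <- generate_survival(config, truths)
  truth <- dplyr::left_join(truths, surv$truth, by = "patient_id")
  out <- list(records = surv$records, truth = truth)
  if (maps) out$studies <- studies
  out
}

#' Generate paired pre/post revascularization studies
#'
#' Pre-revascularization studies carry severe-group defects; the post study
#' is derived from the pre study by one of four archetypes: `complete`
#' (every severe-group pixel redrawn as normal), `partial` (half of them),
#' `failed` (unchanged), `harmed` (a fifth of the normal pixels degraded to
#' mild/moderate). The archetype is recorded in the truth table.
#'
#' @param config A [sim_config()]; `n_patients` is the number of pairs.
#' @param archetype_probs Probabilities for `complete`, `partial`, `failed`,
#'   `harmed`.
#' @param partial_fraction Fraction of severe-region pixels relabelled under
#'   `partial`.
#' @return List: `pre`, `post` (named lists of study tibbles), `truth`
#'   (pair archetypes and true pre fractions).
#' @export
generate_paired_cohort <- function(config,
                                   archetype_probs = c(complete = 0.35,
                                                       partial = 0.35,
                                                       failed = 0.2,
                                                       harmed = 0.1),
                                   partial_fraction = 0.5) {
  set.seed(config$seed)
  n <- config$n_patients
  pair_arch <- sample(names(archetype_probs), n, replace = TRUE,
                      prob = archetype_probs)
  terrs <- c("LAD", "LCx", "RCA")
  pre <- post <- vector("list", n)
  ids <- sprintf("PR%04d", seq_len(n))
  truth <- vector("list", n)
  for (i in seq_len(n)) {
    # harmed pairs start near-normal (procedures on normal CFC); others
    # carry a severe-group defect
    defects <- if (pair_arch[i] == "harmed") NULL else tibble::tibble(
      territory = sample(terrs, 1),
      class = sample(c("MODERATE", "SEVERE", "STEAL"), 1,
                     prob = c(0.35, 0.55, 0.10)),
      extent = stats::runif(1, config$extent_range[1], config$extent_range[2])
    )
    g <- generate_study(config, ids[i], defects)
    pre[[i]] <- g$study
    p <- g$study
    sev_px <- which(g$true_class %in% c("MODERATE", "SEVERE", "STEAL"))
    relabel <- switch(pair_arch[i],
      complete = sev_px,
      partial = sample(sev_px, round(length(sev_px) * partial_fraction)),
      failed = integer(0),
      harmed = integer(0)
    )
    if (length(relabel)) {
      p[relabel, c("rest", "stress")] <-
        draw_class_perfusion("EXCELLENT", length(relabel))
    }
    if (pair_arch[i] == "harmed") {
      norm_px <- which(g$true_class %in% c("EXCELLENT", "ADEQUATE"))
      hit <- sample(norm_px, round(length(norm_px) * 0.2))
      cls <- sample(c("MILD", "MODERATE"), length(hit), replace = TRUE)
      for (cl in unique(cls)) {
        sel <- hit[cls == cl]
        p[sel, c("rest", "stress")] <- draw_class_perfusion(cl, length(sel))
      }
    }
    post[[i]] <- p
    truth[[i]] <- dplyr::mutate(g$true_fractions, archetype = pair_arch[i])
  }
  names(pre) <- names(post) <- ids
  list(pre = pre, post = post, truth = dplyr::bind_rows(truth))
}
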