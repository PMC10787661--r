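output_header <- function(config) {
  paste0("# cfcsurv ", as.character(utils::packageVersion("cfcsurv")),
         " | config_hash=",
         substr(rlang::hash(config), 1, 12))
}

write_with_header <- function(df, path, config) {
  writeLines(output_header(config), path)
  readr::write_csv(df, path, append = TRUE, col_names = TRUE,
                   progress = FALSE)
  invisible(path)
}

#' Map stage: polar maps to CFC summaries and a covariate table
#'
#' Reads every polar-map file, validates the pixel count, builds and
#' summarises the CFC map, and writes per-study class maps and summaries
#' plus one combined covariate table ready for the survival stage.
#'
#' @param paths Character vector of polar-map file paths.
#' @param out_dir Output directory (created if needed).
#' @param rest_floor Rest perfusion floor for CFR, mL/min/g.
#' @param n_expected Expected pixels per map (`NULL` to accept any).
#' @return Invisibly, the combined covariate tibble.
#' @export
run_map <- function(paths, out_dir, rest_floor = 0.1, n_expected = 1344) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- list(stage = "map", rest_floor = rest_floor,
              n_expected = n_expected)
  covs <- purrr::map_dfr(paths, function(p) {
    study <- read_polar_map(p, n_expected = n_expected)
    map <- build_cfc_map(study, rest_floor = rest_floor)
    smry <- summarize_map(map)
    id <- study$patient_id[1]
    write_with_header(
      dplyr::select(map, "pixel", "ring", "sector", "territory", "cfr",
                    "low_rest", "cfc_class"),
      file.path(out_dir, paste0(id, "_cfc_map.csv")), cfg)
    write_with_header(smry, file.path(out_dir, paste0(id, "_summary.csv")),
                      cfg)
    if (any(map$low_rest)) {
      message(id, ": ", sum(map$low_rest), " low-rest pixel(s) floored")
    }
    cfc_covariates(smry)
  })
  write_with_header(covs, file.path(out_dir, "covariates.csv"), cfg)
  invisible(covs)
}

#' Survival stage: cohort table to fitted model and per-patient estimates
#'
#' Applies the >90-day inclusion filter, expands time-dependent
#' revascularization rows, fits the Cox model and writes the coefficient
#' table, the baseline cumulative hazard, and per-patient survival
#' estimates under both pathways.
#'
#' @param cohort Cohort tibble (see [read_cohort()]) or a path to one.
#' @param out_dir Output directory.
#' @param horizon Prediction horizon in years.
#' @return Invisibly, a list with `fit` and `estimates`.
#' @export
run_survival <- function(cohort, out_dir, horizon = 10) {
  if (is.character(cohort)) cohort <- read_cohort(cohort)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- list(stage = "survival", horizon = horizon)
  kept <- apply_inclusion_filter(cohort)
  message(attr(kept, "n_removed"), " record(s) removed by the >90-day ",
          "follow-up filter")
  rows <- expand_time_dependent(kept)
  fit <- fit_cox(rows)
  write_with_header(tidy(fit), file.path(out_dir, "cox_coefficients.csv"),
                    cfg)
  write_with_header(fit$baseline, file.path(out_dir, "baseline_hazard.csv"),
                    cfg)
  est <- dplyr::bind_rows(
    predict_survival(fit, kept, horizon = horizon, pathway = "no_revasc"),
    predict_survival(fit, kept, horizon = horizon, pathway = "revasc_at_t0")
  )
  est$probability <- round(est$probability, 4)
  write_with_header(est, file.path(out_dir, "survival_estimates.csv"), cfg)
  if (any(est$extrapolated)) {
    message("baseline hazard carried forward beyond last event time for ",
            sum(est$extrapolated), " estimate(s)")
  }
  invisible(list(fit = fit, estimates = est))
}

#' Virtual + comparison stage
#'
#' Computes observed and virtual survival probabilities from
#' pre-revascularization covariates and, when paired post studies are
#' supplied, the discordance report, the paired KS severity-histogram
#' comparisons and the Bland-Altman summary of realistic-virtual vs
#' observed-post probabilities.
#'
#' @param fit A `cfc_cox_fit`.
#' @param pre Tibble of pre-revascularization baseline covariates
#'   (`patient_id`, fractions, `age`, `sex`).
#' @param out_dir Output directory.
#' @param post Optional tibble of post-revascularization covariates with
#'   the same columns.
#' @param pre_maps,post_maps Optional named lists of `cfc_map`s for the KS
#'   report.
#' @param horizon Years.
#' @param virtual_mode Redistribution mode, see [realistic_virtual()].
#' @return Invisibly, a list with `virtual`, and when paired:
#'   `discordance`, `ks`, `bland_altman`.
#' @export
run_virtual_and_compare <- function(fit, pre, out_dir, post = NULL,
                                    pre_maps = NULL, post_maps = NULL,
                                    horizon = 10,
                                    virtual_mode = "proportional") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- list(stage = "virtual", horizon = horizon, mode = virtual_mode)
  vr <- virtual_survival(fit, pre, horizon = horizon, mode = virtual_mode)
  out <- list(virtual = vr)
  write_with_header(
    dplyr::mutate(vr, dplyr::across(dplyr::ends_with("_prob"),
                                    ~ round(.x, 4))),
    file.path(out_dir, "virtual_survival.csv"), cfg)
  if (!is.null(post)) {
    # fix the interaction indicator at the baseline (pre) severity so the
    # post-vs-virtual discordance reflects CFC map differences only
    base_ind <- as.integer(
      pre$cfc_severe[match(post$patient_id, pre$patient_id)] > 0)
    p_post <- predict_survival(fit, post, horizon = horizon,
                               pathway = "revasc_at_t0",
                               severe_ind = base_ind)
    disc <- discordance(p_post, vr)
    out$discordance <- disc
    write_with_header(disc$per_patient,
                      file.path(out_dir, "discordance.csv"), cfg)
    p_pre <- predict_survival(fit, pre, horizon = horizon,
                              pathway = "no_revasc")
    pc <- paired_outcome_classification(
      dplyr::left_join(p_pre,
                       dplyr::select(pre, "patient_id", "cfc_severe",
                                     "cfc_normal"),
                       by = "patient_id"),
      p_post)
    out$paired <- pc
    write_with_header(pc$counts, file.path(out_dir, "paired_counts.csv"),
                      cfg)
    ba <- bland_altman(vr$realistic_virtual_prob, p_post$probability)
    out$bland_altman <- ba
    write_with_header(ba, file.path(out_dir, "bland_altman.csv"), cfg)
  } else {
    message("no paired post studies: discordance/KS sections omitted")
  }
  if (!is.null(pre_maps) && !is.null(post_maps)) {
    ks <- purrr::map_dfr(names(pre_maps), function(id) {
      res <- ks_compare(severity_histogram(pre_maps[[id]]),
                        severity_histogram(post_maps[[id]]))
      dplyr::mutate(res, pair_id = id, .before = 1)
    })
    out$ks <- ks
    write_with_header(ks, file.path(out_dir, "ks_paired.csv"), cfg)
  }
  invisible(out)
}
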