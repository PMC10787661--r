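#' Optimal virtual covariates after ideal complete revascularization
#'
#' Replaces the severe CFC fraction with normal CFC: `cfc_severe` becomes 0
#' and its mass moves entirely to `cfc_normal`; mild and scar are unchanged,
#' so the fractions still partition the LV. Models the best-case outcome of
#' complete revascularization of all severely flow-limited myocardium.
#'
#' @param covariates Tibble with `cfc_normal`, `cfc_mild`, `cfc_severe`,
#'   `scar` rows (fractions of LV).
#' @return Tibble of the same shape with the transform applied.
#' @examples
#' optimal_virtual(tibble::tibble(cfc_normal = 0.5, cfc_mild = 0.2,
#'                                cfc_severe = 0.25, scar = 0.05))
#' @export
optimal_virtual <- function(covariates) {
  x <- tibble::as_tibble(covariates)
  check_fractions(x)
  dplyr::mutate(x,
                cfc_normal = .data$cfc_normal + .data$cfc_severe,
                cfc_severe = 0)
}

#' Realistic virtual covariates after typical revascularization
#'
#' Redistributes the severe CFC fraction between normal and mild CFC in
#' proportion to their prevalence outside the severe region, reflecting
#' that real-world revascularization restores severely flow-limited
#' myocardium only to the surrounding mixture of normal and diffusely/mildly
#' diseased tissue. Scar is unchanged. With `mode = "mild_constant"` all of
#' the severe mass goes to normal while mild is frozen (an alternative
#' reading of keeping mild constant). When no normal or mild tissue exists
#' outside the severe region the degenerate rule sends all severe mass to
#' normal and flags the row.
#'
#' @inheritParams optimal_virtual
#' @param mode `"proportional"` (default) or `"mild_constant"`.
#' @return Tibble with the transform applied and a logical `degenerate`
#'   column.
#' @examples
#' realistic_virtual(tibble::tibble(cfc_normal = 0.5, cfc_mild = 0.25,
#'                                  cfc_severe = 0.20, scar = 0.05))
#' @export
realistic_virtual <- function(covariates,
                              mode = c("proportional", "mild_constant")) {
  mode <- match.arg(mode)
  x <- tibble::as_tibble(covariates)
  check_fractions(x)
  n <- x$cfc_normal; m <- x$cfc_mild; s <- x$cfc_severe
  degen <- (n + m) == 0 & s > 0
  if (mode == "mild_constant") {
    x$cfc_normal <- n + s
  } else {
    share <- ifelse(n + m > 0, s / (n + m), 0)
    x$cfc_normal <- n + share * n + ifelse(degen, s, 0)
    x$cfc_mild <- m + share * m
  }
  x$cfc_severe <- 0
  x$degenerate <- degen
  x
}

#' Observed and virtual survival probabilities for one or more patients
#'
#' For each record, predicts the observed survival probability from the
#' unmodified pre-revascularization covariates and the Optimal / Realistic
#' Virtual probabilities from the transformed covariates. All three use the
#' revascularized pathway (revascularization covariate on from time zero) so
#' virtual estimates are directly comparable with post-revascularization
#' observed estimates. The severe indicator driving the
#' revascularization-by-severity interaction is fixed at its baseline
#' (pre-revascularization) value for all three predictions: effect
#' modification is a property of the pre-treatment state, and holding it
#' constant makes the estimates differ only through the CFC fractions. As a
#' consequence, whenever the fitted CFC coefficients satisfy
#' `beta_severe >= beta_mild >= 0` the estimates bracket:
#' optimal >= realistic >= observed.
#'
#' @param fit A `cfc_cox_fit`.
#' @param records Tibble of baseline (pre-revascularization) covariates:
#'   `patient_id`, `cfc_normal`, `cfc_mild`, `cfc_severe`, `scar`, `age`,
#'   `sex`.
#' @param horizon Years (default 10).
#' @param mode Realistic-virtual redistribution mode, see
#'   [realistic_virtual()].
#' @param pathway Pathway used for all three predictions.
#' @return Tibble: `patient_id`, `observed_prob`, `optimal_virtual_prob`,
#'   `realistic_virtual_prob`, `degenerate`, `horizon`.
#' @export
virtual_survival <- function(fit, records, horizon = 10,
                             mode = c("proportional", "mild_constant"),
                             pathway = "revasc_at_t0") {
  mode <- match.arg(mode)
  recs <- tibble::as_tibble(records)
  opt <- optimal_virtual(recs)
  rea <- realistic_virtual(recs, mode = mode)
  base_ind <- as.integer(recs$cfc_severe > 0)
  p_obs <- predict_survival(fit, recs, horizon = horizon, pathway = pathway,
                            severe_ind = base_ind)
  p_opt <- predict_survival(fit, opt, horizon = horizon, pathway = pathway,
                            severe_ind = base_ind)
  p_rea <- predict_survival(fit, rea, horizon = horizon, pathway = pathway,
                            severe_ind = base_ind)
  tibble::tibble(
    patient_id = p_obs$patient_id,
    observed_prob = p_obs$probability,
    optimal_virtual_prob = p_opt$probability,
    realistic_virtual_prob = p_rea$probability,
    degenerate = rea$degenerate,
    horizon = horizon
  )
}

#' Discordance between virtual and observed post-revascularization survival
#'
#' Differences between the virtual probabilities (computed from the
#' pre-revascularization map) and the observed probability computed from the
#' actual post-revascularization map. Positive optimal discordance flags
#' residual diffuse disease, multiple stenosis, or incomplete/failed
#' revascularization.
#'
#' @param observed_post Tibble with `patient_id` and `probability` (observed
#'   post-revascularization survival estimate).
#' @param virtual Tibble from [virtual_survival()] on the
#'   pre-revascularization records.
#' @return List with `per_patient` tibble (`optimal_discordance`,
#'   `realistic_discordance`, `residual_cad_flag`) and `cohort_means`.
#' @export
discordance <- function(observed_post, virtual) {
  if (!setequal(observed_post$patient_id, virtual$patient_id)) {
    stop("pre/post patient IDs do not match", call. = FALSE)
  }
  joined <- dplyr::inner_join(
    virtual,
    dplyr::select(observed_post, "patient_id",
                  observed_post_prob = "probability"),
    by = "patient_id"
  )
  per <- dplyr::mutate(
    joined,
    optimal_discordance = .data$optimal_virtual_prob -
      .data$observed_post_prob,
    realistic_discordance = .data$realistic_virtual_prob -
      .data$observed_post_prob,
    residual_cad_flag = .data$optimal_discordance > 0
  )
  list(
    per_patient = per,
    cohort_means = tibble::tibble(
      mean_optimal_discordance = mean(per$optimal_discordance),
      mean_realistic_discordance = mean(per$realistic_discordance)
    )
  )
}

#' Pixel-level optimal virtual transform
#'
#' Relabels every severe-group pixel (MODERATE, SEVERE, STEAL) of a CFC map
#' as normal; summarising the transformed map yields the same grouped
#' covariates as [optimal_virtual()] applied to the original summary.
#'
#' @param map A `cfc_map`.
#' @return The map with relabelled `cfc_class`.
#' @export
optimal_virtual_map <- function(map) {
  sev <- map$cfc_class %in% c("MODERATE", "SEVERE", "STEAL")
  map$cfc_class[sev] <- "EXCELLENT"
  map
}

check_fractions <- function(x) {
  need <- c("cfc_normal", "cfc_mild", "cfc_severe", "scar")
  missing <- setdiff(need, names(x))
  if (length(missing)) {
    stop("missing covariate column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  v <- as.matrix(x[, need])
  if (any(v < -1e-12) || any(v > 1 + 1e-12)) {
    stop("covariate fractions must lie in [0, 1]", call. = FALSE)
  }
  invisible(x)
}
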