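#' Summarise a CFC map as fractions of the left ventricle
#'
#' Counts pixel labels into per-class fractions (%-of-LV on the 0..1 scale)
#' for the whole LV and for each artery territory, and forms the grouped Cox
#' covariates: `cfc_normal` (EXCELLENT + ADEQUATE, the reference),
#' `cfc_mild` (MILD), `cfc_severe` (MODERATE + SEVERE and, by default,
#' STEAL) and `scar` (SCAR). Both the class fractions and the grouped
#' covariates sum to one on every row.
#'
#' @param map A `cfc_map` tibble from [build_cfc_map()].
#' @param steal_in_severe Count STEAL pixels inside `cfc_severe` (default,
#'   treating steal as the extreme of severe flow limitation)? When `FALSE`
#'   steal becomes its own grouped column `cfc_steal`, so the grouped
#'   covariates still partition the LV.
#' @return Tibble of class `cfc_summary`, one row per region (`"LV"` first,
#'   then each territory): class-fraction columns `excellent` .. `scar_class`,
#'   the grouped covariates, and `n_pixels`.
#' @export
summarize_map <- function(map, steal_in_severe = TRUE) {
  if (nrow(map) == 0) stop("empty CFC map", call. = FALSE)
  stopifnot("cfc_class" %in% names(map))
  regions <- dplyr::bind_rows(
    dplyr::mutate(map, region = "LV"),
    dplyr::mutate(map, region = .data$territory)
  )
  frac_cols <- c("excellent", "adequate", "mild", "moderate", "severe",
                 "steal", "scar_class")
  out <- regions |>
    dplyr::count(.data$region, .data$cfc_class, .drop = FALSE) |>
    dplyr::group_by(.data$region) |>
    dplyr::mutate(n_pixels = sum(.data$n), frac = .data$n / .data$n_pixels) |>
    dplyr::ungroup() |>
    dplyr::select("region", "cfc_class", "n_pixels", "frac") |>
    tidyr::pivot_wider(names_from = "cfc_class", values_from = "frac") |>
    dplyr::rename_with(~ frac_cols, dplyr::all_of(cfc_levels))
  sev_classes <- c("moderate", "severe", if (steal_in_severe) "steal")
  out <- out |>
    dplyr::mutate(
      cfc_normal = .data$excellent + .data$adequate,
      cfc_mild = .data$mild,
      cfc_severe = rowSums(dplyr::pick(dplyr::all_of(sev_classes))),
      scar = .data$scar_class
    )
  if (!steal_in_severe) {
    out <- dplyr::mutate(out, cfc_steal = .data$steal, .after = "cfc_severe")
  }
  out <- dplyr::arrange(out, .data$region != "LV", .data$region)
  if ("patient_id" %in% names(map)) {
    out <- dplyr::mutate(out, patient_id = map$patient_id[1], .before = 1)
  }
  class(out) <- c("cfc_summary", class(out))
  out
}

#' Grouped Cox covariates from a summary
#'
#' Convenience accessor: the whole-LV row of a [summarize_map()] result,
#' reduced to the covariate columns used by the survival model.
#'
#' @param summary A `cfc_summary` tibble.
#' @return One-row tibble with `cfc_normal`, `cfc_mild`, `cfc_severe`,
#'   `scar` (and `patient_id` when present).
#' @export
cfc_covariates <- function(summary) {
  lv <- dplyr::filter(summary, .data$region == "LV")
  cols <- intersect(c("patient_id", "cfc_normal", "cfc_mild", "cfc_severe",
                      "scar"), names(lv))
  tibble::as_tibble(lv[, cols])
}

#' Discriminate microvascular dysfunction from focal/diffuse CAD
#'
#' A study-level call on one perfusion study: with flow limitation present
#' (mild-or-worse CFC beyond `extent_threshold` of the LV), a preserved mean
#' subendocardial/subepicardial stress ratio (within the healthy reference
#' band of mean +/- 2 SD) and no material severe component indicates
#' microvascular dysfunction — pressure, and hence the transmural gradient,
#' is maintained; a reduced ratio or a focal severe component indicates
#' focal or diffuse epicardial CAD. The healthy band defaults emulate a
#' young-volunteer reference cohort.
#'
#' @param summary `cfc_summary` for the study.
#' @param study Perfusion study tibble with `subendo_stress` and
#'   `subepi_stress` layers.
#' @param healthy_ref_mean,healthy_ref_sd Mean and SD of the
#'   subendo/subepi stress ratio in healthy volunteers.
#' @param extent_threshold Fraction of LV above which a CFC group counts as
#'   materially present.
#' @return One-row tibble: `call` (one of `FOCAL_OR_DIFFUSE_CAD`,
#'   `MICROVASCULAR_DYSFUNCTION`, `NO_FLOW_LIMITATION`),
#'   `subendo_ratio_mean`, `healthy_ref_mean`, `healthy_ref_sd`.
#' @export
classify_flow_limitation <- function(summary, study,
                                     healthy_ref_mean = 1.0,
                                     healthy_ref_sd = 0.075,
                                     extent_threshold = 0.05) {
  if (!all(c("subendo_stress", "subepi_stress") %in% names(study))) {
    stop("subendocardial/subepicardial stress layers are required",
         call. = FALSE)
  }
  stopifnot(healthy_ref_sd > 0)
  lv <- dplyr::filter(summary, .data$region == "LV")
  nonscar <- study$subepi_stress > 0 &
    !(study$rest <= .scar_thresh & study$stress <= .scar_thresh)
  ratio <- mean(study$subendo_stress[nonscar] / study$subepi_stress[nonscar])
  limited <- (lv$cfc_mild + lv$cfc_severe) >= extent_threshold
  in_band <- abs(ratio - healthy_ref_mean) <= 2 * healthy_ref_sd
  call <- if (!limited) {
    "NO_FLOW_LIMITATION"
  } else if (lv$cfc_severe < extent_threshold && in_band) {
    "MICROVASCULAR_DYSFUNCTION"
  } else {
    "FOCAL_OR_DIFFUSE_CAD"
  }
  tibble::tibble(
    patient_id = if ("patient_id" %in% names(lv)) lv$patient_id else NA_character_,
    call = call,
    subendo_ratio_mean = ratio,
    healthy_ref_mean = healthy_ref_mean,
    healthy_ref_sd = healthy_ref_sd
  )
}
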