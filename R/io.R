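#' Read a polar-map file
#'
#' Reads one patient's perfusion polar map from delimited text (comma or
#' tab): one row per pixel with columns `pixel_index` (0-based), `ring`,
#' `sector`, `territory`, `rest`, `stress` and optionally `subendo_stress`,
#' `subepi_stress`. A header row is required.
#'
#' @param path File path.
#' @param patient_id Patient identifier attached to the study; defaults to
#'   the file name without extension.
#' @param n_expected Expected pixel count (`NULL` to skip the check).
#' @return Perfusion-study tibble, one row per pixel.
#' @export
read_polar_map <- function(path, patient_id = NULL, n_expected = NULL) {
  df <- readr::read_delim(path, show_col_types = FALSE, progress = FALSE)
  need <- c("pixel_index", "ring", "sector", "territory", "rest", "stress")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop(path, ": missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(n_expected) && nrow(df) != n_expected) {
    stop(path, ": expected ", n_expected, " pixel rows, found ", nrow(df),
         " (deficit ", n_expected - nrow(df), ")", call. = FALSE)
  }
  bad <- which(!is.finite(df$rest) | !is.finite(df$stress) |
                 df$rest < 0 | df$stress < 0)
  if (length(bad)) {
    stop(path, ": invalid perfusion value at data line ", bad[1],
         call. = FALSE)
  }
  study <- dplyr::rename(df, pixel = "pixel_index")
  if (is.null(patient_id)) {
    patient_id <- sub("\\.[^.]*$", "", basename(path))
  }
  dplyr::mutate(study, patient_id = patient_id, .before = 1)
}

#' Write a polar-map file
#'
#' @param study Perfusion-study tibble.
#' @param path Output path (CSV with header).
#' @export
write_polar_map <- function(study, path) {
  out <- dplyr::rename(study, pixel_index = "pixel")
  keep <- intersect(c("pixel_index", "ring", "sector", "territory", "rest",
                      "stress", "subendo_stress", "subepi_stress"),
                    names(out))
  readr::write_csv(out[, keep], path, progress = FALSE)
  invisible(path)
}

#' Read a cohort table
#'
#' Delimited text with one row per patient: `patient_id`, `age`, `sex`
#' (`male`/`female`), `followup_years`, `death` (0/1), `revasc_years`
#' (empty when no revascularization), `cfc_normal`, `cfc_mild`,
#' `cfc_severe`, `scar`, `prior_revasc` (0/1).
#'
#' @param path File path.
#' @return Cohort tibble; `revasc_years` is `NA` where absent.
#' @export
read_cohort <- function(path) {
  df <- readr::read_delim(path, show_col_types = FALSE, progress = FALSE)
  need <- c("patient_id", "age", "sex", "followup_years", "death",
            "cfc_normal", "cfc_mild", "cfc_severe", "scar")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop(path, ": missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (!"revasc_years" %in% names(df)) df$revasc_years <- NA_real_
  if (!"prior_revasc" %in% names(df)) df$prior_revasc <- 0L
  tibble::as_tibble(df)
}

#' Write a cohort table
#'
#' @param cohort Cohort tibble.
#' @param path Output path (CSV; `NA` revascularization times written as
#'   empty fields).
#' @export
write_cohort <- function(cohort, path) {
  readr::write_csv(cohort, path, na = "", progress = FALSE)
  invisible(path)
}
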