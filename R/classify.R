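#' Ordered CFC severity classes
#'
#' The seven coronary flow capacity classes in increasing severity order.
#' Severity rank runs 0 (EXCELLENT) to 6 (SCAR); SCAR ranks most severe for
#' histogram ordering.
#'
#' @export
cfc_levels <- c("EXCELLENT", "ADEQUATE", "MILD", "MODERATE", "SEVERE",
                "STEAL", "SCAR")

# CFR class breakpoints (exclusive lower bounds of EXCELLENT..MODERATE);
# SEVERE additionally requires CFR >= 1.
.cfr_breaks <- c(2.9, 2.38, 1.6, 1.27)
# Stress-perfusion class breakpoints, mL/min/g (same exclusive-lower-bound
# semantics).
.stress_breaks <- c(2.17, 1.82, 1.09, 0.83)
.scar_thresh <- 0.3

#' Coronary flow reserve per pixel
#'
#' CFR = stress / rest, with rest floored at `rest_floor` before division so
#' near-zero rest noise cannot produce unbounded ratios. Pixels whose raw
#' rest value fell below the floor are flagged (`low_rest`); scar detection
#' elsewhere always uses the raw rest value.
#'
#' @param study A perfusion study tibble (see [read_polar_map()] or
#'   [generate_study()]): one row per pixel with `rest` and `stress` in
#'   mL/min/g.
#' @param rest_floor Minimum rest perfusion used as the divisor (mL/min/g).
#' @return The study tibble with `cfr` and `low_rest` columns appended.
#' @export
compute_cfr <- function(study, rest_floor = 0.1) {
  stopifnot(rest_floor > 0)
  check_perfusion(study)
  dplyr::mutate(
    study,
    low_rest = .data$rest < rest_floor,
    cfr = .data$stress / pmax(.data$rest, rest_floor)
  )
}

#' Classify pixels into CFC severity classes
#'
#' Deterministic per-pixel label with precedence: scar first (both rest and
#' stress perfusion at or below 0.3 mL/min/g, a fixed defect independent of
#' CFR), then myocardial steal (CFR < 1), then the ranked classes. For the
#' ranked classes the pixel is scored on two scales — CFR against breakpoints
#' 2.9 / 2.38 / 1.6 / 1.27 and stress perfusion against 2.17 / 1.82 / 1.09 /
#' 0.83 mL/min/g, each with exclusive lower bounds — and receives the more
#' severe of the two single-scale ranks, so discordant CFR/stress
#' combinations are always covered.
#'
#' @param cfr Per-pixel coronary flow reserve (unitless, >= 0).
#' @param stress Per-pixel stress perfusion, mL/min/g.
#' @param rest Per-pixel rest perfusion, mL/min/g (raw, used only for scar).
#' @return Ordered factor with levels [cfc_levels].
#' @examples
#' classify_pixel(3.2, 2.5, 0.78)  # EXCELLENT
#' classify_pixel(1.1, 0.5, 0.45)  # SEVERE
#' classify_pixel(3.5, 0.9, 0.257) # MODERATE: stress rank dominates
#' @export
classify_pixel <- function(cfr, stress, rest) {
  n <- length(cfr)
  if (length(stress) != n || length(rest) != n) {
    stop("cfr, stress and rest must have equal length", call. = FALSE)
  }
  if (any(!is.finite(cfr)) || any(!is.finite(stress)) || any(!is.finite(rest))) {
    stop("non-finite classifier input", call. = FALSE)
  }
  if (any(cfr < 0) || any(stress < 0) || any(rest < 0)) {
    stop("negative perfusion or CFR value", call. = FALSE)
  }
  # rank 0..4 on each scale: number of breakpoints at or above the value
  # (exclusive lower bounds: value > break means it clears that class)
  cfr_rank <- findInterval(-cfr, -.cfr_breaks)          # > semantics via negation
  stress_rank <- findInterval(-stress, -.stress_breaks)
  rank <- pmax(cfr_rank, stress_rank)
  lab <- cfc_levels[rank + 1L]
  lab[cfr < 1] <- "STEAL"
  lab[rest <= .scar_thresh & stress <= .scar_thresh] <- "SCAR"
  factor(lab, levels = cfc_levels, ordered = TRUE)
}

#' Build a CFC map for one study
#'
#' Computes per-pixel CFR and classifies every pixel, returning the study
#' tibble with `cfr`, `low_rest` and `cfc_class` columns — one label per
#' pixel, spatially indexed by the layout columns.
#'
#' @inheritParams compute_cfr
#' @return Tibble of class `cfc_map`: one row per pixel with `cfc_class`
#'   (ordered factor) appended.
#' @export
build_cfc_map <- function(study, rest_floor = 0.1) {
  m <- compute_cfr(study, rest_floor)
  m <- dplyr::mutate(
    m, cfc_class = classify_pixel(.data$cfr, .data$stress, .data$rest)
  )
  class(m) <- c("cfc_map", class(m))
  m
}

#' Numeric severity rank of CFC classes
#'
#' @param x Factor or character vector of CFC class labels.
#' @return Integer rank 0 (EXCELLENT) .. 6 (SCAR).
#' @export
cfc_rank <- function(x) {
  match(as.character(x), cfc_levels) - 1L
}

#' Locate a classification boundary by bisection
#'
#' Sweeps one classifier input while holding the others fixed and bisects to
#' the value at which the pixel label changes. Used to verify that the class
#' transitions sit exactly at the published CFR / stress-perfusion / scar
#' thresholds.
#'
#' @param axis One of `"cfr"` (vary CFR at fixed stress, rest = stress/CFR),
#'   `"stress"` (vary stress at fixed CFR, rest = stress/CFR) or
#'   `"scar_diagonal"` (rest = stress = v).
#' @param lower,upper Bracketing interval; the label must differ at the ends.
#' @param at Fixed value of the held input (stress for `axis = "cfr"`, CFR
#'   for `axis = "stress"`; ignored for the scar diagonal).
#' @param tol Bisection tolerance.
#' @return The boundary location (midpoint of the final bracket).
#' @export
class_boundary_bisect <- function(axis = c("cfr", "stress", "scar_diagonal"),
                                  lower, upper, at = NULL, tol = 1e-6) {
  axis <- match.arg(axis)
  label_at <- switch(axis,
    cfr = function(v) classify_pixel(v, at, at / v),
    stress = function(v) classify_pixel(at, v, v / at),
    scar_diagonal = function(v) classify_pixel(1, v, v)
  )
  lo <- lower; hi <- upper
  f_lo <- label_at(lo)
  if (label_at(hi) == f_lo) {
    stop("no label transition inside the bracket", call. = FALSE)
  }
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (label_at(mid) == f_lo) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

check_perfusion <- function(study) {
  need <- c("rest", "stress")
  missing <- setdiff(need, names(study))
  if (length(missing)) {
    stop("perfusion study lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  for (col in need) {
    v <- study[[col]]
    if (any(!is.finite(v)) || any(v < 0)) {
      stop("column '", col, "' must be finite and >= 0", call. = FALSE)
    }
  }
  invisible(study)
}
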