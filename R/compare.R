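#' Severity histogram of a CFC map or summary
#'
#' Fractions of LV per CFC class ordered by severity rank (EXCELLENT = 0 ..
#' SCAR = 6), with the cumulative curve used for Kolmogorov-Smirnov
#' comparisons.
#'
#' @param x A `cfc_map` (pixel tibble with `cfc_class`), a `cfc_summary`,
#'   or a numeric vector of 7 class fractions in severity order (summing to
#'   1).
#' @param n_pixels Pixel count behind the fractions (only used for the
#'   numeric-vector form; defaults to 1344).
#' @return Tibble of class `severity_histogram`: `cfc_class`, `rank`,
#'   `fraction`, `cumulative`, and attribute `n_pixels`.
#' @export
severity_histogram <- function(x, n_pixels = 1344) {
  if (is.numeric(x)) {
    stopifnot(length(x) == 7, abs(sum(x) - 1) < 1e-9)
    frac <- as.numeric(x)
    n <- n_pixels
  } else if ("cfc_class" %in% names(x)) {
    counts <- table(factor(x$cfc_class, levels = cfc_levels))
    frac <- as.numeric(counts) / sum(counts)
    n <- sum(counts)
  } else {
    lv <- dplyr::filter(x, .data$region == "LV")
    frac <- unlist(lv[, c("excellent", "adequate", "mild", "moderate",
                          "severe", "steal", "scar_class")], use.names = FALSE)
    n <- lv$n_pixels
  }
  out <- tibble::tibble(
    cfc_class = factor(cfc_levels, levels = cfc_levels, ordered = TRUE),
    rank = 0:6,
    fraction = frac,
    cumulative = cumsum(frac)
  )
  attr(out, "n_pixels") <- n
  class(out) <- c("severity_histogram", class(out))
  out
}

# asymptotic two-sided two-sample KS tail probability
ks_pvalue <- function(d, n_eff) {
  if (d <= 0) return(1)
  lambda <- sqrt(n_eff) * d
  k <- 1:100
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * lambda^2))
  min(1, max(0, p))
}

#' Kolmogorov-Smirnov comparison of two severity histograms
#'
#' `D` is the maximum absolute difference between the two cumulative
#' severity curves over the seven ordered classes. The p-value uses the
#' asymptotic two-sample KS distribution with effective sample size
#' `n_a * n_b / (n_a + n_b)` (pixel counts); it is nominal, since polar-map
#' pixels are spatially correlated.
#'
#' @param a,b `severity_histogram` objects on the same category axis.
#' @return Tibble: `statistic` (D), `p_value`, `n_a`, `n_b`.
#' @export
ks_compare <- function(a, b) {
  if (!identical(as.character(a$cfc_class), as.character(b$cfc_class))) {
    stop("severity histograms are on different category axes", call. = FALSE)
  }
  d <- max(abs(a$cumulative - b$cumulative))
  n_a <- attr(a, "n_pixels"); n_b <- attr(b, "n_pixels")
  n_eff <- n_a * n_b / (n_a + n_b)
  tibble::tibble(statistic = d, p_value = ks_pvalue(d, n_eff),
                 n_a = n_a, n_b = n_b)
}

#' Classify paired pre/post survival changes
#'
#' Per-pair difference in predicted survival probability (post minus pre),
#' classified better / worse / unchanged (within `unchanged_band`), overall
#' and within the baseline strata used for reporting: severe CFC present,
#' no severe CFC, and normal CFC over at least 90% of LV.
#'
#' @param pre,post Tibbles with `patient_id` and `probability`; `pre` must
#'   also carry the baseline covariates `cfc_severe` and `cfc_normal` for
#'   stratification.
#' @param unchanged_band Absolute probability difference treated as
#'   unchanged.
#' @return List with `per_pair` tibble (`delta`, `classification`,
#'   `stratum`) and `counts` tibble by stratum (including `"all"`).
#' @export
paired_outcome_classification <- function(pre, post, unchanged_band = 0.005) {
  if (!setequal(pre$patient_id, post$patient_id)) {
    stop("pre/post patient IDs do not match", call. = FALSE)
  }
  joined <- dplyr::inner_join(
    dplyr::select(pre, "patient_id", pre_prob = "probability",
                  "cfc_severe", "cfc_normal"),
    dplyr::select(post, "patient_id", post_prob = "probability"),
    by = "patient_id"
  )
  per <- dplyr::mutate(
    joined,
    delta = .data$post_prob - .data$pre_prob,
    classification = dplyr::case_when(
      abs(.data$delta) < unchanged_band ~ "unchanged",
      .data$delta > 0 ~ "better",
      TRUE ~ "worse"
    ),
    stratum = dplyr::case_when(
      .data$cfc_normal >= 0.9 ~ "normal_ge_90pct",
      .data$cfc_severe > 0 ~ "severe_present",
      TRUE ~ "non_severe"
    )
  )
  count_one <- function(df, label) {
    tibble::tibble(
      stratum = label,
      n = nrow(df),
      better = sum(df$classification == "better"),
      worse = sum(df$classification == "worse"),
      unchanged = sum(df$classification == "unchanged")
    )
  }
  counts <- dplyr::bind_rows(
    count_one(per, "all"),
    purrr::map_dfr(split(per, per$stratum),
                   ~ count_one(.x, .x$stratum[1]))
  )
  list(per_pair = per, counts = counts)
}

#' Bland-Altman agreement between paired probability estimates
#'
#' @param x,y Numeric vectors of equal length (>= 2).
#' @return Tibble: `bias` (mean of `x - y`), `sd_diff`, `lower_loa`,
#'   `upper_loa` (bias +/- 1.96 SD).
#' @export
bland_altman <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch", call. = FALSE)
  if (length(x) < 2) stop("need at least 2 pairs", call. = FALSE)
  d <- x - y
  bias <- mean(d)
  s <- stats::sd(d)
  tibble::tibble(bias = bias, sd_diff = s,
                 lower_loa = bias - 1.96 * s, upper_loa = bias + 1.96 * s)
}

#' Serial coefficient of variance between repeated acquisitions
#'
#' Test-retest precision of per-pixel perfusion: the SD of paired
#' differences divided by sqrt(2) (per-measurement SD), over the pooled
#' mean, as a percent.
#'
#' @param repeat_a,repeat_b Per-pixel perfusion vectors of equal length.
#' @return Tibble: `cv_percent`, `pooled_mean`, `undefined` flag (pooled
#'   mean zero).
#' @export
serial_cv <- function(repeat_a, repeat_b) {
  if (length(repeat_a) != length(repeat_b)) {
    stop("length mismatch", call. = FALSE)
  }
  pooled <- mean(c(repeat_a, repeat_b))
  if (pooled == 0) {
    return(tibble::tibble(cv_percent = NA_real_, pooled_mean = 0,
                          undefined = TRUE))
  }
  s <- stats::sd(repeat_a - repeat_b) / sqrt(2)
  tibble::tibble(cv_percent = 100 * s / pooled, pooled_mean = pooled,
                 undefined = FALSE)
}
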