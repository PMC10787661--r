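#' Follow-up inclusion filter
#'
#' Drops patients with 90 days or less of follow-up, the minimum required
#' for a survival record to enter the Cox model.
#'
#' @param records Cohort tibble (see [read_cohort()]).
#' @param min_days Minimum follow-up in days (exclusive).
#' @return Filtered tibble; the number of removed records is attached as
#'   attribute `n_removed`.
#' @export
apply_inclusion_filter <- function(records, min_days = 90) {
  keep <- records$followup_years > min_days / 365.25
  out <- records[keep, , drop = FALSE]
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Expand a cohort into counting-process rows
#'
#' Each patient contributes one interval `(0, followup]` when never
#' revascularized, or two intervals split at the revascularization time with
#' the time-dependent `revasc` covariate switching from 0 to 1. The death
#' indicator is attached only to the final interval. `severe_ind` marks any
#' severe CFC involvement (`cfc_severe > severe_threshold`) and drives the
#' revascularization-by-severity interaction.
#'
#' @param records Cohort tibble passing the inclusion filter.
#' @param severe_threshold Fraction of LV above which the severe indicator
#'   is set (default 0: any severe pixels).
#' @return Tibble with `tstart`, `tstop`, `event`, `revasc`, `severe_ind`
#'   and the fixed covariates.
#' @export
expand_time_dependent <- function(records, severe_threshold = 0) {
  r <- records
  bad <- !is.na(r$revasc_years) & r$revasc_years >= r$followup_years
  if (any(bad)) {
    warning(sum(bad), " record(s) with revascularization at/after end of ",
            "follow-up treated as unrevascularized single intervals")
    r$revasc_years[bad] <- NA_real_
  }
  if (any(!is.na(r$revasc_years) & r$revasc_years <= 0)) {
    stop("revascularization time must be positive", call. = FALSE)
  }
  base <- dplyr::mutate(
    r,
    severe_ind = as.integer(.data$cfc_severe > severe_threshold),
    sex_male = as.integer(.data$sex == "male")
  )
  no_rv <- dplyr::filter(base, is.na(.data$revasc_years)) |>
    dplyr::mutate(tstart = 0, tstop = .data$followup_years,
                  event = .data$death, revasc = 0L)
  rv <- dplyr::filter(base, !is.na(.data$revasc_years))
  pre <- dplyr::mutate(rv, tstart = 0, tstop = .data$revasc_years,
                       event = 0L, revasc = 0L)
  post <- dplyr::mutate(rv, tstart = .data$revasc_years,
                        tstop = .data$followup_years,
                        event = .data$death, revasc = 1L)
  out <- dplyr::bind_rows(no_rv, pre, post) |>
    dplyr::arrange(.data$patient_id, .data$tstart)
  cols <- c("patient_id", "tstart", "tstop", "event", "revasc", "severe_ind",
            "cfc_mild", "cfc_severe", "scar", "age", "sex_male")
  out[, c(cols, setdiff(names(out), cols))]
}

cox_covariate_names <- c("cfc_mild", "cfc_severe", "scar", "age", "sex_male",
                         "revasc", "revasc_x_severe")

#' Fit the CFC Cox proportional-hazards model
#'
#' Multivariable Cox regression of all-cause mortality on the grouped CFC
#' size-severity covariates (fractions of LV: `cfc_mild`, `cfc_severe`,
#' `scar`, with normal CFC the implicit reference), age, sex, the
#' time-dependent revascularization covariate and its interaction with the
#' severe-CFC indicator. Fitting uses the Efron approximation for ties on
#' the counting-process rows; the Breslow baseline cumulative hazard (at
#' covariate zero) is stored as a step function for survival prediction.
#'
#' @param rows Counting-process tibble from [expand_time_dependent()].
#' @param covariates Character vector of covariate column names; the last
#'   term `revasc_x_severe` is constructed as `revasc * severe_ind`.
#' @param ties Tie-handling approximation passed to the partial likelihood
#'   (`"efron"` default, or `"breslow"`).
#' @return Object of class `cfc_cox_fit`: list with `coefficients`, `se`,
#'   `vcov`, `baseline` (tibble `time`, `hazard`), `n_subjects`, `n_events`,
#'   `loglik`, `concordance` and the underlying `survival::coxph` fit.
#' @export
fit_cox <- function(rows, covariates = cox_covariate_names,
                    ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  if (sum(rows$event) < 2) {
    stop("need at least 2 events to fit the Cox model", call. = FALSE)
  }
  df <- as.data.frame(rows)
  df$revasc_x_severe <- df$revasc * df$severe_ind
  for (v in covariates) {
    if (!v %in% names(df)) stop("unknown covariate: ", v, call. = FALSE)
    if (stats::var(df[[v]]) == 0) {
      stop("constant covariate: ", v, call. = FALSE)
    }
  }
  fml <- stats::as.formula(paste(
    "survival::Surv(tstart, tstop, event) ~",
    paste(covariates, collapse = " + ")
  ))
  fit <- survival::coxph(fml, data = df, ties = ties,
                         control = survival::coxph.control(iter.max = 50))
  if (any(is.na(stats::coef(fit)))) {
    stop("Cox fit failed (singular or separated covariates)", call. = FALSE)
  }
  bh <- survival::basehaz(fit, centered = FALSE)
  structure(list(
    coefficients = stats::coef(fit),
    se = sqrt(diag(stats::vcov(fit))),
    vcov = stats::vcov(fit),
    baseline = tibble::tibble(time = bh$time, hazard = bh$hazard),
    n_subjects = length(unique(rows$patient_id)),
    n_events = sum(rows$event),
    loglik = fit$loglik[2],
    concordance = unname(fit$concordance["concordance"]),
    covariates = covariates,
    coxph = fit
  ), class = "cfc_cox_fit")
}

#' @export
print.cfc_cox_fit <- function(x, ...) {
  cat("CFC Cox model:", x$n_subjects, "subjects,", x$n_events, "events\n")
  print(tibble::tibble(term = names(x$coefficients),
                       estimate = unname(x$coefficients),
                       std_error = unname(x$se)))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the coefficients of a CFC Cox fit
#'
#' @param x A `cfc_cox_fit`.
#' @param conf_level Confidence level for the Wald interval.
#' @param ... Unused.
#' @return Tibble with `term`, `estimate`, `std_error`, `statistic`,
#'   `p_value`, `conf_low`, `conf_high`.
#' @method tidy cfc_cox_fit
#' @export
tidy.cfc_cox_fit <- function(x, conf_level = 0.95, ...) {
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  est <- unname(x$coefficients)
  se <- unname(x$se)
  tibble::tibble(
    term = names(x$coefficients),
    estimate = est,
    std_error = se,
    statistic = est / se,
    p_value = 2 * stats::pnorm(-abs(est / se)),
    conf_low = est - z * se,
    conf_high = est + z * se
  )
}

#' One-row model summary of a CFC Cox fit
#'
#' @param x A `cfc_cox_fit`.
#' @param ... Unused.
#' @method glance cfc_cox_fit
#' @export
glance.cfc_cox_fit <- function(x, ...) {
  tibble::tibble(
    n_subjects = x$n_subjects,
    n_events = x$n_events,
    log_likelihood = x$loglik,
    concordance = x$concordance
  )
}

baseline_cumhaz <- function(fit, t) {
  bl <- fit$baseline
  idx <- findInterval(t, bl$time)
  extrap <- t > max(bl$time)
  h <- ifelse(idx == 0, 0, bl$hazard[pmax(idx, 1L)])
  list(hazard = h, extrapolated = extrap)
}

#' Predict survival probability from a fitted CFC Cox model
#'
#' Computes `S(t | x) = exp(-H0(t) exp(x'beta))` with the stored Breslow
#' baseline. The revascularization covariate is set by `pathway`: 0
#' throughout (`"no_revasc"`) or 1 from time zero (`"revasc_at_t0"`), with
#' the severity interaction following. Beyond the last event time the
#' baseline hazard is carried forward and the estimate is flagged.
#'
#' @param fit A `cfc_cox_fit`.
#' @param covariates Tibble with one row per patient: `cfc_mild`,
#'   `cfc_severe`, `scar`, `age`, `sex` (or `sex_male`), optionally
#'   `patient_id`.
#' @param horizon Prediction horizon in years (default 10).
#' @param pathway `"no_revasc"` or `"revasc_at_t0"`.
#' @param severe_threshold Threshold defining the severe indicator for the
#'   interaction term.
#' @param severe_ind Optional fixed value(s) for the severe indicator used
#'   in the revascularization interaction, overriding the value derived
#'   from `covariates`. Counterfactual predictions fix this at the baseline
#'   state so that effect modification is not altered by the covariate
#'   substitution.
#' @return Tibble: `patient_id`, `horizon`, `probability`, `pathway`,
#'   `extrapolated`.
#' @export
predict_survival <- function(fit, covariates, horizon = 10,
                             pathway = c("no_revasc", "revasc_at_t0"),
                             severe_threshold = 0, severe_ind = NULL) {
  pathway <- match.arg(pathway)
  x <- tibble::as_tibble(covariates)
  if (!"sex_male" %in% names(x)) {
    if (!"sex" %in% names(x)) {
      stop("covariates need 'sex' or 'sex_male'", call. = FALSE)
    }
    x$sex_male <- as.integer(x$sex == "male")
  }
  x$severe_ind <- if (is.null(severe_ind)) {
    as.integer(x$cfc_severe > severe_threshold)
  } else {
    as.integer(severe_ind)
  }
  x$revasc <- if (pathway == "revasc_at_t0") 1L else 0L
  x$revasc_x_severe <- x$revasc * x$severe_ind
  missing <- setdiff(fit$covariates, names(x))
  if (length(missing)) {
    stop("unknown covariate(s) in model spec: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  xm <- as.matrix(x[, fit$covariates])
  lp <- drop(xm %*% fit$coefficients)
  h0 <- baseline_cumhaz(fit, horizon)
  tibble::tibble(
    patient_id = if ("patient_id" %in% names(x)) x$patient_id else
      seq_len(nrow(x)),
    horizon = horizon,
    probability = exp(-h0$hazard * exp(lp)),
    pathway = pathway,
    extrapolated = h0$extrapolated
  )
}

#' Predicted mortality contrast across severity and pathway strata
#'
#' Average predicted mortality `1 - S(horizon)` in the four strata formed by
#' severe-CFC involvement and revascularization pathway, with the relative
#' mortality reduction from revascularization inside each severity stratum.
#'
#' @param fit A `cfc_cox_fit`.
#' @param records Cohort tibble (baseline covariates).
#' @param horizon Years.
#' @param severe_threshold Severe-indicator threshold.
#' @return Tibble: `stratum`, `pathway`, `n`, `mean_mortality`, plus
#'   `relative_reduction` (revasc vs no-revasc) per stratum.
#' @export
cohort_mortality_contrast <- function(fit, records, horizon = 10,
                                      severe_threshold = 0) {
  recs <- tibble::as_tibble(records)
  recs$stratum <- ifelse(recs$cfc_severe > severe_threshold,
                         "severe", "non_severe")
  out <- purrr::map_dfr(c("no_revasc", "revasc_at_t0"), function(pw) {
    p <- predict_survival(fit, recs, horizon = horizon, pathway = pw,
                          severe_threshold = severe_threshold)
    tibble::tibble(stratum = recs$stratum, pathway = pw,
                   mortality = 1 - p$probability)
  }) |>
    dplyr::group_by(.data$stratum, .data$pathway) |>
    dplyr::summarise(n = dplyr::n(),
                     mean_mortality = mean(.data$mortality),
                     .groups = "drop")
  wide <- tidyr::pivot_wider(out, id_cols = "stratum",
                             names_from = "pathway",
                             values_from = "mean_mortality")
  red <- dplyr::mutate(
    wide,
    relative_reduction = (.data$no_revasc - .data$revasc_at_t0) /
      .data$no_revasc
  )
  dplyr::left_join(out, red[, c("stratum", "relative_reduction")],
                   by = "stratum")
}

#' Cox partial log-likelihood and score by direct risk-set sums
#'
#' Brute-force evaluation of the counting-process Cox partial likelihood
#' with the Efron tie correction: loops over distinct event times, forms the
#' risk set `{i : tstart < t <= tstop}` explicitly and accumulates the Efron
#' downweighted denominators. Independent of the fitting route; used to
#' verify fitted models on small cohorts.
#'
#' @param beta Coefficient vector.
#' @param rows Counting-process tibble with `tstart`, `tstop`, `event` and
#'   covariate columns.
#' @param covariates Covariate column names matching `beta` (a
#'   `revasc_x_severe` column is derived if requested and absent).
#' @return List with `loglik` (scalar) and `score` (gradient vector).
#' @export
cox_partial_loglik <- function(beta, rows, covariates = cox_covariate_names) {
  df <- as.data.frame(rows)
  if ("revasc_x_severe" %in% covariates && !"revasc_x_severe" %in% names(df)) {
    df$revasc_x_severe <- df$revasc * df$severe_ind
  }
  X <- as.matrix(df[, covariates])
  eta <- drop(X %*% beta)
  w <- exp(eta)
  loglik <- 0
  score <- numeric(length(beta))
  for (t in sort(unique(df$tstop[df$event == 1]))) {
    D <- which(df$event == 1 & df$tstop == t)
    R <- which(df$tstart < t & t <= df$tstop)
    d <- length(D)
    sR <- sum(w[R]); sD <- sum(w[D])
    xR <- colSums(w[R] * X[R, , drop = FALSE])
    xD <- colSums(w[D] * X[D, , drop = FALSE])
    loglik <- loglik + sum(eta[D])
    score <- score + colSums(X[D, , drop = FALSE])
    for (l in seq_len(d) - 1L) {
      denom <- sR - (l / d) * sD
      loglik <- loglik - log(denom)
      score <- score - (xR - (l / d) * xD) / denom
    }
  }
  list(loglik = loglik, score = score)
}
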