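# Independent classification oracle: a literal transcription of the printed
# class ranges as an if-chain lookup, coded separately from the package's
# rank-based classifier.
oracle_classify_one <- function(cfr, stress, rest) {
  if (rest <= 0.3 && stress <= 0.3) return("SCAR")
  if (cfr < 1.0) return("STEAL")
  cfr_class <-
    if (cfr > 2.9) "EXCELLENT"
    else if (cfr > 2.38) "ADEQUATE"
    else if (cfr > 1.6) "MILD"
    else if (cfr > 1.27) "MODERATE"
    else "SEVERE"
  stress_class <-
    if (stress > 2.17) "EXCELLENT"
    else if (stress > 1.82) "ADEQUATE"
    else if (stress > 1.09) "MILD"
    else if (stress > 0.83) "MODERATE"
    else "SEVERE"
  order7 <- c("EXCELLENT", "ADEQUATE", "MILD", "MODERATE", "SEVERE")
  order7[max(match(cfr_class, order7), match(stress_class, order7))]
}

oracle_classify <- function(cfr, stress, rest) {
  vapply(seq_along(cfr),
         function(i) oracle_classify_one(cfr[i], stress[i], rest[i]),
         character(1))
}

# brute-force two-sample KS statistic: explicit loop over categories
brute_ks_d <- function(frac_a, frac_b) {
  best <- 0
  ca <- 0; cb <- 0
  for (i in seq_along(frac_a)) {
    ca <- ca + frac_a[i]
    cb <- cb + frac_b[i]
    if (abs(ca - cb) > best) best <- abs(ca - cb)
  }
  best
}

# random covariate fractions on the 4-simplex (gamma normalisation)
random_fractions <- function(n) {
  g <- matrix(stats::rgamma(4 * n, shape = 1), ncol = 4)
  g <- g / rowSums(g)
  tibble::tibble(cfc_normal = g[, 1], cfc_mild = g[, 2],
                 cfc_severe = g[, 3], scar = g[, 4])
}

# small uniform perfusion study on a reduced layout
uniform_study <- function(rest, stress, n_rings = 3, n_sectors = 8,
                          patient_id = "t") {
  lay <- polar_layout(n_rings, n_sectors)
  dplyr::mutate(lay, patient_id = patient_id, rest = rest, stress = stress,
                .before = 1)
}
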