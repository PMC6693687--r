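# Independent oracles and fixture builders shared across the suite.
# The oracles deliberately use naive loop-based code paths so they share
# nothing with the package implementation.

# Brute-force Passing-Bablok line: enumerate every pairwise slope with
# explicit loops, apply the published shifted-median rule by hand.
pb_oracle_line <- function(x, y) {
  slopes <- c()
  for (i in seq_along(x)) {
    for (j in seq_along(x)) {
      if (j <= i) next
      dx <- x[j] - x[i]
      dy <- y[j] - y[i]
      if (dx == 0) next # undefined slope
      s <- dy / dx
      if (s == -1) next
      slopes <- c(slopes, s)
    }
  }
  slopes <- sort(slopes)
  n_s <- length(slopes)
  k <- 0
  for (s in slopes) if (s < -1) k <- k + 1
  pick <- function(i) slopes[min(max(i, 1), n_s)]
  b <- if (n_s %% 2 == 1) {
    pick((n_s + 1) / 2 + k)
  } else {
    (pick(n_s / 2 + k) + pick(n_s / 2 + 1 + k)) / 2
  }
  resid <- sort(y - b * x)
  m <- length(resid)
  a <- if (m %% 2 == 1) resid[(m + 1) / 2] else (resid[m / 2] + resid[m / 2 + 1]) / 2
  c(intercept = a, slope = b)
}

# sort-and-pick median, independent of stats::median
median_oracle <- function(v) {
  v <- sort(v)
  n <- length(v)
  if (n %% 2 == 1) v[(n + 1) / 2] else (v[n / 2] + v[n / 2 + 1]) / 2
}

# two-point line equation, independent of stats::approx
interp_oracle <- function(knot_ages, knot_vals, age) {
  i <- max(which(knot_ages <= age))
  if (knot_ages[i] == age) {
    return(knot_vals[i])
  }
  x0 <- knot_ages[i]
  x1 <- knot_ages[i + 1]
  knot_vals[i] + (knot_vals[i + 1] - knot_vals[i]) * (age - x0) / (x1 - x0)
}

# deterministic miniature study: n cases, one protocol, organs covering a
# named site, the marrow label and two remainder organs
make_cases <- function(n = 6, protocol = "abdomen_pelvis", kv = rep(120, n),
                       stomach_impact = seq_len(n),
                       stomach_scale = c(male = 1.1, female = 1.2)) {
  ids <- sprintf("C%02d", seq_len(n))
  build_rows <- function(software, sex_variant, organ_doses, eff) {
    purrr::imap_dfr(organ_doses, function(dose_vec, org) {
      tibble::tibble(
        case_id = ids, protocol = protocol, provider_id = "P01",
        kv = kv, ctdi_vol = 10, software = software,
        sex_variant = sex_variant, effective_dose = eff,
        organ = org, dose_msv = dose_vec
      )
    })
  }
  eff_imp <- 5 + seq_len(n) / 10
  imp <- build_rows("impact", "hermaphrodite", list(
    "stomach" = stomach_impact,
    "bone marrow" = stomach_impact / 2,
    "pancreas" = rep(4, n),
    "kidneys" = rep(6, n)
  ), eff_imp)
  nci <- purrr::map_dfr(c("male", "female"), function(sx) {
    sc <- stomach_scale[[sx]]
    build_rows("ncict", sx, list(
      "stomach" = stomach_impact * sc,
      "active marrow" = stomach_impact / 2 * sc,
      "pancreas" = rep(4 * sc, n),
      "kidneys" = rep(6 * sc, n)
    ), eff_imp * sc)
  })
  dplyr::bind_rows(imp, nci)
}

# design with an exact inter-method model for identity checks
identity_design <- function(seed = 1L, slope = 1, intercept = 0, tau = 0) {
  d <- ctdoserisk::study_design(protocols = "abdomen_pelvis", seed = seed)
  d$site_models$intercept <- intercept
  d$site_models$slope <- slope
  d$site_models$residual_sd <- tau
  d
}
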