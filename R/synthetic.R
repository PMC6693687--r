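# Synthetic paired-dose study generator.  Emulates the sampling frame of
# the reference study (8 providers x 20 cases per protocol, modal 120 kV)
# with a per-site linear inter-method model (systematic intercept A,
# proportional slope B, residual sd tau) so that every downstream stage
# -- kV filtering, median tables, Bland-Altman, Passing-Bablok recovery,
# LAR projection -- is testable without the original scan records.

#' Describe a synthetic study design
#'
#' The defaults emulate the reference study's frame: 8 providers
#' contributing 20 cases per protocol (160 cases) with tube voltage drawn
#' from a 120/100 kV mixture whose mode is 120 kV.  The mathematical-
#' phantom dose for each organ is log-normal with its median anchored at
#' the study's published median for that protocol/site (organs with a
#' published median of zero are floored at 0.005 mSv); the voxelised-
#' phantom dose follows `y = A + B x + e` per site and sex, with slope
#' defaulting to the ratio of the published medians, intercept 0, and
#' residual sd equal to 2% of the site median (the order of the published
#' residual standard deviations).
#'
#' @param protocols Protocols to simulate.
#' @param n_providers,cases_per_provider Sampling frame (defaults 8 x 20).
#' @param kv_levels Named probabilities of tube voltages; must sum to 1
#'   and have a unique mode.
#' @param sdlog Log-scale sd of the organ dose distribution (default 0.4,
#'   a typical spread for protocol-level CT dose audits).
#' @param site_models Optional tibble `protocol, sex, site, meanlog,
#'   sdlog, intercept, slope, residual_sd` overriding the derived models.
#' @param seed Integer seed; the generator is deterministic given it.
#' @return Object of class `study_design` (a list).
#' @export
study_design <- function(protocols = ctdoserisk::protocols(),
                         n_providers = 8, cases_per_provider = 20,
                         kv_levels = c("120" = 0.8, "100" = 0.2),
                         sdlog = 0.4, site_models = NULL, seed = 1L) {
  if (abs(sum(kv_levels) - 1) > 1e-8) {
    abort("kv_levels probabilities must sum to 1", class = "ctdoserisk_config_error")
  }
  if (sum(kv_levels == max(kv_levels)) > 1) {
    abort("kv_levels must have a unique modal voltage", class = "ctdoserisk_config_error")
  }
  if (n_providers < 1 || cases_per_provider < 1) {
    abort("counts must be >= 1", class = "ctdoserisk_config_error")
  }
  if (is.null(site_models)) {
    site_models <- default_site_models(protocols, sdlog)
  }
  if (any(site_models$slope <= 0) || any(site_models$residual_sd < 0)) {
    abort("site models need slope > 0 and residual_sd >= 0",
      class = "ctdoserisk_config_error"
    )
  }
  structure(
    list(
      protocols = protocols, n_providers = n_providers,
      cases_per_provider = cases_per_provider, kv_levels = kv_levels,
      site_models = site_models, seed = as.integer(seed)
    ),
    class = "study_design"
  )
}

# anchor the generator at the published medians: median(lognormal) = exp(meanlog)
default_site_models <- function(protocols, sdlog) {
  study_median_doses() %>%
    dplyr::filter(
      .data$protocol %in% protocols, .data$site != "effective_dose"
    ) %>%
    tidyr::pivot_wider(names_from = "software", values_from = "median_msv") %>%
    dplyr::mutate(
      impact = pmax(.data$impact, 0.005),
      ncict = pmax(.data$ncict, 0.005),
      meanlog = log(.data$impact),
      sdlog = sdlog,
      intercept = 0,
      slope = .data$ncict / .data$impact,
      # residual scale ~2% of the dose magnitude, the order of the
      # published residual standard deviations for these protocols
      residual_sd = 0.02 * .data$impact
    ) %>%
    dplyr::select(
      "protocol", "sex", "site", "meanlog", "sdlog",
      "intercept", "slope", "residual_sd"
    )
}

# positive draws by resampling rather than clipping (no point mass at 0);
# draw(idx) must return one value per requested position
truncated_positive <- function(n, draw) {
  out <- draw(seq_len(n))
  bad <- which(out < 0)
  guard <- 0
  while (length(bad) > 0 && guard < 1000) {
    out[bad] <- draw(bad)
    bad <- which(out < 0)
    guard <- guard + 1
  }
  pmax(out, 0)
}

#' Generate paired measurements with a known linear relationship
#'
#' Draws `x` from a positive distribution and sets
#' `y = intercept + slope * x + e` with zero-mean Gaussian noise of sd
#' `residual_sd`; negative draws are resampled so both axes stay
#' positive.  This provides the systematic-plus-proportional structure
#' Passing-Bablok regression is designed to detect.
#'
#' @param n Number of pairs (>= 3).
#' @param intercept,slope,residual_sd Linear model parameters; `slope > 0`,
#'   `residual_sd >= 0`.
#' @param x_model List `list(dist = "lognormal", meanlog, sdlog)` or
#'   `list(dist = "uniform", min, max)` describing the x distribution.
#' @param seed Integer seed.
#' @return Tibble `x, y`.
#' @export
generate_pairs <- function(n, intercept, slope, residual_sd,
                           x_model = list(dist = "lognormal", meanlog = log(10), sdlog = 0.4),
                           seed = 1L) {
  if (n < 3) abort("n must be >= 3", class = "ctdoserisk_config_error")
  if (slope <= 0) abort("slope must be > 0", class = "ctdoserisk_config_error")
  if (residual_sd < 0) {
    abort("residual_sd must be >= 0", class = "ctdoserisk_config_error")
  }
  draw_x <- switch(x_model$dist,
    lognormal = function(idx) rlnorm(length(idx), x_model$meanlog, x_model$sdlog),
    uniform = function(idx) runif(length(idx), x_model$min, x_model$max),
    abort(paste0("unknown x_model distribution '", x_model$dist, "'"),
      class = "ctdoserisk_config_error"
    )
  )
  withr::with_seed(seed, {
    x <- truncated_positive(n, draw_x)
    y <- truncated_positive(
      n, function(idx) intercept + slope * x[idx] + rnorm(length(idx), 0, residual_sd)
    )
    tibble::tibble(x = x, y = y)
  })
}

# independent substream per protocol x provider so adding providers or
# protocols never perturbs existing draws
substream_seed <- function(seed, protocol_idx, provider_idx) {
  as.integer((seed + 99991 * protocol_idx + 7919 * provider_idx) %% .Machine$integer.max)
}

#' Generate a synthetic paired-dose study
#'
#' Produces the long case tibble of [read_case_csv()]: per case one
#' hermaphrodite record for the mathematical-phantom program and one
#' record per voxelised reference phantom (male and female), mirroring
#' software that reports both.  Effective dose is a fixed
#' positively-weighted sum of the site doses — a plausible paired scalar,
#' not an attempt at tissue weighting.
#'
#' @param design A [study_design()].
#' @return Long case tibble.
#' @export
generate_study <- function(design) {
  stopifnot(inherits(design, "study_design"))
  kv_vals <- as.numeric(names(design$kv_levels))
  rows <- list()
  for (pi in seq_along(design$protocols)) {
    prot <- design$protocols[pi]
    models <- design$site_models[design$site_models$protocol == prot, ]
    if (nrow(models) == 0) {
      abort(paste0("no site models for protocol '", prot, "'"),
        class = "ctdoserisk_config_error"
      )
    }
    for (qi in seq_len(design$n_providers)) {
      rows[[length(rows) + 1]] <- withr::with_seed(
        substream_seed(design$seed, pi, qi),
        generate_provider_block(design, prot, qi, models, kv_vals)
      )
    }
  }
  dplyr::bind_rows(rows)
}

generate_provider_block <- function(design, prot, qi, models, kv_vals) {
  n <- design$cases_per_provider
  provider <- sprintf("P%02d", qi)
  kv <- sample(kv_vals, n, replace = TRUE, prob = design$kv_levels)
  ctdi <- rlnorm(n, log(10), 0.3)
  # one hermaphrodite draw per case and organ; organs shared across sexes
  # draw from the male-model meanlog (identical for shared organs)
  organ_for_site <- c(
    stomach = "stomach", colon = "colon", liver = "liver", lung = "lung",
    prostate = "prostate", uterus = "uterus", ovary = "ovaries",
    bladder = "bladder", breast = "breast", thyroid = "thyroid"
  )
  case_ids <- sprintf("%s-%s-%03d", prot, provider, seq_len(n))

  out <- list()
  x_by_site <- list() # hermaphrodite (impact) dose per site
  base_models <- models %>%
    dplyr::distinct(.data$site, .data$meanlog, .data$sdlog)
  for (i in seq_len(nrow(base_models))) {
    s <- base_models$site[i]
    x_by_site[[s]] <- truncated_positive(
      n, function(idx) rlnorm(length(idx), base_models$meanlog[i], base_models$sdlog[i])
    )
  }

  site_to_impact_organ <- function(s) {
    if (s == "leukaemia") "bone marrow" else if (s == "other") NA else organ_for_site[[s]]
  }
  site_to_ncict_organ <- function(s) {
    if (s == "leukaemia") "active marrow" else if (s == "other") NA else organ_for_site[[s]]
  }
  remainder <- c("pancreas", "kidneys", "adrenals")

  # impact (hermaphrodite) rows
  imp <- purrr::imap_dfr(x_by_site, function(xv, s) {
    if (s == "other") {
      # remainder organs scatter around the site-level draw
      purrr::map_dfr(remainder, function(org) {
        tibble::tibble(
          case_id = case_ids, organ = org,
          dose_msv = truncated_positive(
            n, function(idx) xv[idx] * exp(rnorm(length(idx), 0, 0.1))
          )
        )
      })
    } else {
      tibble::tibble(
        case_id = case_ids, organ = site_to_impact_organ(s), dose_msv = xv
      )
    }
  })
  eff_w <- 0.08 # fixed positive effective-dose weight per site dose
  eff_imp <- rep(0, n)
  for (s in names(x_by_site)) eff_imp <- eff_imp + eff_w * x_by_site[[s]]
  # kv/ctdi/effective are per-case: join on case_id
  meta <- tibble::tibble(
    case_id = case_ids, kv = kv, ctdi_vol = ctdi, effective_dose = eff_imp
  )
  out$impact <- imp %>%
    dplyr::left_join(meta, by = "case_id") %>%
    dplyr::mutate(
      protocol = prot, provider_id = provider,
      software = "impact", sex_variant = "hermaphrodite"
    )

  # ncict rows per sex via the inter-method model
  ncict_rows <- purrr::map_dfr(c("male", "female"), function(sx) {
    mods <- models[models$sex == sx, ]
    eff_n <- rep(0, n)
    block <- purrr::map_dfr(seq_len(nrow(mods)), function(i) {
      s <- mods$site[i]
      if (!s %in% cancer_sites(sx)) {
        return(tibble::tibble())
      }
      xv <- x_by_site[[s]]
      yv <- truncated_positive(
        n,
        function(idx) {
          mods$intercept[i] + mods$slope[i] * xv[idx] +
            rnorm(length(idx), 0, mods$residual_sd[i])
        }
      )
      eff_n <<- eff_n + eff_w * yv
      if (s == "other") {
        purrr::map_dfr(remainder, function(org) {
          tibble::tibble(
            case_id = case_ids, organ = org,
            dose_msv = truncated_positive(
            n, function(idx) yv[idx] * exp(rnorm(length(idx), 0, 0.1))
          )
          )
        })
      } else {
        tibble::tibble(
          case_id = case_ids, organ = site_to_ncict_organ(s), dose_msv = yv
        )
      }
    })
    block %>%
      dplyr::left_join(
        tibble::tibble(
          case_id = case_ids, kv = kv, ctdi_vol = ctdi, effective_dose = eff_n
        ),
        by = "case_id"
      ) %>%
      dplyr::mutate(
        protocol = prot, provider_id = provider,
        software = "ncict", sex_variant = sx
      )
  })

  dplyr::bind_rows(out$impact, ncict_rows) %>%
    dplyr::select(dplyr::all_of(c(case_meta_cols, "organ", "dose_msv")))
}

#' Generate a synthetic risk-coefficient fixture
#'
#' A complete sex x site x knot-age coefficient grid with positive values
#' that decrease monotonically in exposure age for the solid sites,
#' qualitatively matching the shape of the vendored incidence table.  A
#' test stand-in, not a transcription.
#'
#' @param seed Integer seed.
#' @return Coefficient tibble (see [load_coefficients()]).
#' @export
generate_coefficient_fixture <- function(seed = 1L) {
  ages <- beir_knot_ages
  withr::with_seed(seed, {
    grid <- purrr::map_dfr(c("male", "female"), function(sx) {
      purrr::map_dfr(cancer_sites(sx), function(s) {
        start <- exp(runif(1, log(50), log(1500)))
        decay <- runif(1, 0.6, 0.95)
        vals <- start * decay^(seq_along(ages) - 1)
        tibble::tibble(sex = sx, site = s, age = ages, coefficient = vals)
      })
    })
  })
  validate_coefficients(grid)
}
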