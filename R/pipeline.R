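# End-to-end orchestration: simulate -> compare -> lar.  Each step reads
# and writes plain-text files so runs are reproducible and scriptable;
# the thin command-line wrapper in inst/scripts/ctdoserisk.R maps these
# functions onto shell subcommands.

resolve_config <- function(config) {
  if (is.character(config)) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  if (!is.list(config)) {
    abort("config must be a list or a path to a JSON file",
      class = "ctdoserisk_config_error"
    )
  }
  config
}

cfg <- function(config, name, default) {
  if (!is.null(config[[name]])) config[[name]] else default
}

#' Simulate a synthetic study and write it to disk
#'
#' Writes the case CSV plus a JSON echo of the design parameters;
#' deterministic under `seed`.
#'
#' @param config List (or path to JSON) with optional elements
#'   `out_dir`, `seed`, `protocols`, `n_providers`, `cases_per_provider`,
#'   `kv_levels` (named probabilities), `sdlog`.
#' @return Named character vector of the written paths, invisibly.
#' @export
run_simulate <- function(config = list()) {
  config <- resolve_config(config)
  out_dir <- cfg(config, "out_dir", ".")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  kv <- cfg(config, "kv_levels", c("120" = 0.8, "100" = 0.2))
  design <- study_design(
    protocols = cfg(config, "protocols", protocols()),
    n_providers = cfg(config, "n_providers", 8),
    cases_per_provider = cfg(config, "cases_per_provider", 20),
    kv_levels = unlist(kv),
    sdlog = cfg(config, "sdlog", 0.4),
    seed = cfg(config, "seed", 1L)
  )
  cases <- generate_study(design)
  paths <- c(
    cases = file.path(out_dir, "cases.csv"),
    design = file.path(out_dir, "design.json")
  )
  write_case_csv(cases, paths[["cases"]])
  jsonlite::write_json(
    design[c("protocols", "n_providers", "cases_per_provider", "kv_levels", "seed")],
    paths[["design"]],
    auto_unbox = TRUE, pretty = TRUE
  )
  invisible(paths)
}

#' Run the method-comparison stage
#'
#' Reads a case CSV, restricts to the modal tube voltage per protocol,
#' computes the median dose table with its difference column, the
#' reference-denominated Bland-Altman summaries (per-case effective dose
#' and per-median organ dose), and Passing-Bablok fits (with log
#' fallback) per protocol x sex x site on the case-level pairs.
#'
#' @param config List (or JSON path) with `cases` (case CSV path;
#'   defaults to `<out_dir>/cases.csv`), optional `out_dir`, `alpha`,
#'   `aliases` (alias JSON path).
#' @return Named character vector of the written paths, invisibly.
#' @export
run_compare <- function(config = list()) {
  config <- resolve_config(config)
  out_dir <- cfg(config, "out_dir", ".")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  alpha <- cfg(config, "alpha", 0.05)
  aliases <- if (!is.null(config$aliases)) {
    read_organ_aliases(config$aliases)
  } else {
    default_organ_aliases()
  }
  cases <- read_case_csv(cfg(config, "cases", file.path(out_dir, "cases.csv")))
  cases <- filter_modal_kv(cases)

  medians <- median_dose_table(cases, aliases)
  diffs <- median_differences(medians)
  paths <- c(
    medians = file.path(out_dir, "medians.csv"),
    differences = file.path(out_dir, "differences.csv"),
    bland_altman = file.path(out_dir, "bland_altman.json"),
    passing_bablok = file.path(out_dir, "passing_bablok.json")
  )
  write_median_table(medians, paths[["medians"]])
  readr::write_csv(
    dplyr::mutate(diffs, dplyr::across(dplyr::where(is.numeric), ~ round(.x, 2))),
    paths[["differences"]]
  )

  # per-case effective-dose agreement plus per-median organ agreement
  eff <- cases %>%
    dplyr::distinct(
      .data$protocol, .data$case_id, .data$software, .data$sex_variant,
      .data$effective_dose
    ) %>%
    tidyr::pivot_wider(
      names_from = c("software", "sex_variant"), values_from = "effective_dose"
    ) %>%
    dplyr::mutate(
      ncict = average_effective_dose(.data$ncict_male, .data$ncict_female)
    )
  ba <- lapply(split(eff, eff$protocol), function(d) {
    glance(bland_altman(d, impact_hermaphrodite, ncict))
  })
  med_ba <- medians %>%
    dplyr::filter(.data$sex %in% c("male", "female")) %>%
    tidyr::pivot_wider(names_from = "software", values_from = "median_msv")
  ba_med <- lapply(
    split(med_ba, list(med_ba$protocol, med_ba$sex)),
    function(d) glance(bland_altman(d, impact, ncict))
  )
  jsonlite::write_json(
    list(effective_dose_by_case = ba, organ_medians = ba_med),
    paths[["bland_altman"]],
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )

  site_doses <- case_site_doses(cases, aliases) %>%
    tidyr::pivot_wider(names_from = "software", values_from = "dose_msv")
  fits <- site_doses %>%
    dplyr::group_by(.data$protocol, .data$sex, .data$site) %>%
    dplyr::group_modify(function(d, key) {
      fit <- tryCatch(
        suppressWarnings(pb_with_fallback(d, impact, ncict, alpha = alpha)),
        ctdoserisk_degenerate = function(e) NULL
      )
      if (is.null(fit)) {
        return(tibble::tibble(equation = NA_character_))
      }
      dplyr::bind_cols(
        tibble::tibble(
          equation = pb_equation(fit),
          intercept = fit$intercept[["estimate"]],
          intercept_lo = fit$intercept[["lower"]],
          intercept_hi = fit$intercept[["upper"]],
          slope = fit$slope[["estimate"]],
          slope_lo = fit$slope[["lower"]],
          slope_hi = fit$slope[["upper"]]
        ),
        glance(fit)
      )
    }) %>%
    dplyr::ungroup()
  jsonlite::write_json(fits, paths[["passing_bablok"]],
    auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null"
  )
  invisible(paths)
}

#' Run the risk-projection stage
#'
#' Reads a median dose table and a risk-coefficient file and writes the
#' LAR curves (long CSV `protocol,sex,software,age,site,lar_per_100k`)
#' plus a summary JSON holding, per protocol and sex, the
#' reference-denominated %-higher range over the exposure ages and the
#' per-site contribution shares for both programs.
#'
#' @param config List (or JSON path) with `medians` (median table CSV;
#'   defaults to `<out_dir>/medians.csv`), optional `coefficients`
#'   (coefficient file; defaults to the vendored incidence table),
#'   `ages` (default 18:80), `out_dir`.
#' @return Named character vector of the written paths, invisibly.
#' @export
run_lar <- function(config = list()) {
  config <- resolve_config(config)
  out_dir <- cfg(config, "out_dir", ".")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  medians <- read_median_table(
    cfg(config, "medians", file.path(out_dir, "medians.csv"))
  )
  coefs <- if (!is.null(config$coefficients)) {
    load_coefficients(config$coefficients)
  } else {
    beir_coefficients()
  }
  ages <- cfg(config, "ages", 18:80)

  combos <- medians %>%
    dplyr::filter(.data$sex %in% c("male", "female")) %>%
    dplyr::distinct(.data$protocol, .data$sex)
  curves <- list()
  summaries <- list()
  rows <- list()
  for (i in seq_len(nrow(combos))) {
    prot <- combos$protocol[i]
    sx <- combos$sex[i]
    cv <- lapply(c("impact", "ncict"), function(sw) {
      lar_curve(medians, coefs, sx, ages = ages, protocol = prot, software = sw)
    })
    names(cv) <- c("impact", "ncict")
    disparity <- pct_higher_curve(cv$ncict, cv$impact)
    key <- paste(prot, sx, sep = ".")
    summaries[[key]] <- list(
      pct_higher = as.list(attr(disparity, "summary")),
      contributions = lapply(cv, function(curve) {
        stats::setNames(
          as.list(site_contributions(curve)$pct),
          site_contributions(curve)$site
        )
      })
    )
    for (sw in names(cv)) {
      rows[[paste(key, sw)]] <- cv[[sw]] %>%
        dplyr::mutate(protocol = prot, sex = sx, software = sw)
    }
  }
  paths <- c(
    curves = file.path(out_dir, "lar_curves.csv"),
    summary = file.path(out_dir, "lar_summary.json")
  )
  readr::write_csv(
    dplyr::bind_rows(rows)[, c(
      "protocol", "sex", "software", "age", "site", "lar_per_100k"
    )],
    paths[["curves"]]
  )
  jsonlite::write_json(summaries, paths[["summary"]],
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(paths)
}
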