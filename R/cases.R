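# Case-level paired dose records: CSV I/O, modal-kV filtering, aggregation
# to median dose tables, and the printed difference column.
#
# In-memory representation of a study is a long tibble with one row per
# case x software x sex_variant x organ:
#   case_id, protocol, provider_id, kv, ctdi_vol, software, sex_variant,
#   effective_dose, organ, dose_msv
# The on-disk dialect is wide (one column per organ label, NA where an
# organ is not reported by that software).

case_meta_cols <- c(
  "case_id", "protocol", "provider_id", "kv", "ctdi_vol",
  "software", "sex_variant", "effective_dose"
)

validate_cases <- function(cases) {
  missing <- setdiff(c(case_meta_cols, "organ", "dose_msv"), names(cases))
  if (length(missing) > 0) {
    abort(
      paste0("case table is missing columns: ", paste(missing, collapse = ", ")),
      class = "ctdoserisk_schema_error"
    )
  }
  if (any(cases$dose_msv < 0, na.rm = TRUE) ||
    any(cases$effective_dose < 0, na.rm = TRUE)) {
    abort("doses must be non-negative", class = "ctdoserisk_domain_error")
  }
  bad <- setdiff(unique(cases$protocol), protocols())
  if (length(bad) > 0) {
    abort(paste0("unknown protocol(s): ", paste(bad, collapse = ", ")),
      class = "ctdoserisk_schema_error"
    )
  }
  invisible(cases)
}

#' Read a case-level paired dose CSV
#'
#' One row per case x software x sex-variant with one column per organ
#' label.  The hermaphrodite sex variant belongs to the mathematical
#' phantom program (`impact`); `male`/`female` to the voxelised program
#' (`ncict`).
#'
#' @param path CSV path (UTF-8, header required).
#' @return Long tibble with one row per case x software x sex-variant x
#'   organ, columns `case_id, protocol, provider_id, kv, ctdi_vol,
#'   software, sex_variant, effective_dose, organ, dose_msv`.
#' @export
read_case_csv <- function(path) {
  wide <- readr::read_csv(path, show_col_types = FALSE, comment = "#")
  missing <- setdiff(case_meta_cols, names(wide))
  if (length(missing) > 0) {
    abort(
      paste0("case CSV is missing columns: ", paste(missing, collapse = ", ")),
      class = "ctdoserisk_schema_error"
    )
  }
  long <- wide %>%
    tidyr::pivot_longer(
      cols = -dplyr::all_of(case_meta_cols),
      names_to = "organ", values_to = "dose_msv", values_drop_na = TRUE
    )
  validate_cases(long)
  long
}

#' Write a case-level paired dose CSV
#'
#' Inverse of [read_case_csv()]; doses are written at full precision.
#'
#' @param cases Long case tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_case_csv <- function(cases, path) {
  validate_cases(cases)
  wide <- cases %>%
    tidyr::pivot_wider(
      id_cols = dplyr::all_of(case_meta_cols),
      names_from = "organ", values_from = "dose_msv"
    )
  readr::write_csv(wide, path, na = "")
  invisible(path)
}

#' Restrict cases to the modal tube voltage
#'
#' Within each protocol only cases scanned at the most frequent tube
#' voltage are retained, removing kV-dependent dose-ratio effects from the
#' software comparison.  A tied mode is an error rather than a silent
#' choice.
#'
#' @param cases Long case tibble.
#' @return The filtered tibble, original row order preserved.
#' @export
filter_modal_kv <- function(cases) {
  validate_cases(cases)
  if (nrow(cases) == 0) {
    abort("no cases supplied", class = "ctdoserisk_domain_error")
  }
  keep <- rep(FALSE, nrow(cases))
  for (prot in unique(cases$protocol)) {
    in_prot <- cases$protocol == prot
    per_case <- cases[in_prot, c("case_id", "kv")] %>% dplyr::distinct()
    tab <- table(per_case$kv)
    top <- names(tab)[tab == max(tab)]
    if (length(top) > 1) {
      abort(
        paste0(
          "tied modal tube voltage for protocol '", prot, "': ",
          paste(top, collapse = ", "), " kV"
        ),
        class = "ctdoserisk_tied_mode"
      )
    }
    keep[in_prot] <- cases$kv[in_prot] == as.numeric(top)
  }
  cases[keep, , drop = FALSE]
}

#' Per-case dose by BEIR VII category
#'
#' Maps organ labels onto cancer sites and aggregates to one dose per
#' case x sex x software x site.  Organs sharing a named category are
#' summed; remainder organs are averaged into `other`.  The hermaphrodite
#' doses of the mathematical phantom are duplicated to both sexes so that
#' they can be paired with the sex-specific voxelised results.
#'
#' @param cases Long case tibble.
#' @param aliases Organ alias table ([read_organ_aliases()]).
#' @return Tibble `case_id, protocol, provider_id, sex, software, site,
#'   dose_msv`.
#' @export
case_site_doses <- function(cases, aliases = default_organ_aliases()) {
  validate_cases(cases)
  mapped <- cases %>%
    dplyr::group_by(.data$software) %>%
    dplyr::mutate(
      site = map_organ_label(.data$organ, unique(.data$software), aliases)
    ) %>%
    dplyr::ungroup()
  # hermaphrodite doses pair with both sexes
  sexed <- dplyr::bind_rows(
    mapped %>%
      dplyr::filter(.data$sex_variant == "hermaphrodite") %>%
      tidyr::crossing(sex = c("male", "female")),
    mapped %>%
      dplyr::filter(.data$sex_variant %in% c("male", "female")) %>%
      dplyr::mutate(sex = .data$sex_variant)
  )
  sexed %>%
    dplyr::filter(purrr::map2_lgl(
      .data$site, .data$sex,
      ~ .x %in% cancer_sites(.y)
    )) %>%
    dplyr::group_by(
      .data$case_id, .data$protocol, .data$provider_id,
      .data$sex, .data$software, .data$site
    ) %>%
    dplyr::summarise(
      # named categories sum their organs, `other` averages them
      dose_msv = if (unique(.data$site) == "other") {
        mean(.data$dose_msv)
      } else {
        sum(.data$dose_msv)
      },
      .groups = "drop"
    )
}

#' Median dose table for a study
#'
#' Collapses (kV-filtered) cases to the median organ equivalent dose per
#' protocol x sex x software x BEIR VII category, plus the gender-neutral
#' effective dose (sex `"neutral"`, site `"effective_dose"`).  Named
#' categories take the median over per-case doses; `other` is the mean of
#' the per-organ medians of the remainder organs.  The voxelised program's
#' effective dose is the per-case average of its male and female results.
#' Even-count medians are the mean of the two central order statistics.
#'
#' @param cases Long case tibble (already restricted to the modal kV).
#' @param aliases Organ alias table.
#' @return Tibble `protocol, sex, software, site, median_msv, n_cases`.
#' @export
median_dose_table <- function(cases, aliases = default_organ_aliases()) {
  validate_cases(cases)
  mapped <- cases %>%
    dplyr::group_by(.data$software) %>%
    dplyr::mutate(
      site = map_organ_label(.data$organ, unique(.data$software), aliases)
    ) %>%
    dplyr::ungroup()

  for (prot in unique(mapped$protocol)) {
    sub <- mapped[mapped$protocol == prot, ]
    has_imp <- any(sub$software == "impact" & sub$sex_variant == "hermaphrodite")
    has_m <- any(sub$software == "ncict" & sub$sex_variant == "male")
    has_f <- any(sub$software == "ncict" & sub$sex_variant == "female")
    if (!has_imp || !has_m || !has_f) {
      abort(
        paste0(
          "protocol '", prot, "' lacks a required software/sex block ",
          "(need impact hermaphrodite and ncict male + female)"
        ),
        class = "ctdoserisk_domain_error"
      )
    }
  }

  n_cases <- mapped %>%
    dplyr::distinct(.data$protocol, .data$case_id) %>%
    dplyr::count(.data$protocol, name = "n_cases")

  sexed <- dplyr::bind_rows(
    mapped %>%
      dplyr::filter(.data$sex_variant == "hermaphrodite") %>%
      tidyr::crossing(sex = c("male", "female")),
    mapped %>%
      dplyr::filter(.data$sex_variant %in% c("male", "female")) %>%
      dplyr::mutate(sex = .data$sex_variant)
  ) %>%
    dplyr::filter(purrr::map2_lgl(.data$site, .data$sex, ~ .x %in% cancer_sites(.y)))

  named <- sexed %>%
    dplyr::filter(.data$site != "other") %>%
    dplyr::group_by(
      .data$protocol, .data$sex, .data$software, .data$site, .data$case_id
    ) %>%
    dplyr::summarise(dose_msv = sum(.data$dose_msv), .groups = "drop_last") %>%
    dplyr::summarise(median_msv = median(.data$dose_msv), .groups = "drop")

  other <- sexed %>%
    dplyr::filter(.data$site == "other") %>%
    dplyr::group_by(
      .data$protocol, .data$sex, .data$software, .data$organ
    ) %>%
    dplyr::summarise(organ_median = median(.data$dose_msv), .groups = "drop_last") %>%
    dplyr::summarise(median_msv = compute_other_dose(.data$organ_median), .groups = "drop") %>%
    dplyr::mutate(site = "other")

  eff_imp <- mapped %>%
    dplyr::filter(.data$software == "impact", .data$sex_variant == "hermaphrodite") %>%
    dplyr::distinct(.data$protocol, .data$case_id, .data$effective_dose) %>%
    dplyr::group_by(.data$protocol) %>%
    dplyr::summarise(median_msv = median(.data$effective_dose), .groups = "drop") %>%
    dplyr::mutate(software = "impact")

  eff_ncict <- mapped %>%
    dplyr::filter(.data$software == "ncict") %>%
    dplyr::distinct(
      .data$protocol, .data$case_id, .data$sex_variant, .data$effective_dose
    ) %>%
    tidyr::pivot_wider(names_from = "sex_variant", values_from = "effective_dose") %>%
    dplyr::mutate(eff = average_effective_dose(.data$male, .data$female)) %>%
    dplyr::group_by(.data$protocol) %>%
    dplyr::summarise(median_msv = median(.data$eff), .groups = "drop") %>%
    dplyr::mutate(software = "ncict")

  eff <- dplyr::bind_rows(eff_imp, eff_ncict) %>%
    dplyr::mutate(sex = "neutral", site = "effective_dose")

  dplyr::bind_rows(named, other, eff) %>%
    dplyr::left_join(n_cases, by = "protocol") %>%
    dplyr::select(
      "protocol", "sex", "software", "site", "median_msv", "n_cases"
    ) %>%
    dplyr::arrange(.data$protocol, .data$sex, .data$software, .data$site)
}

#' Difference between the two programs' medians for one cell
#'
#' Returns `median_ncict - median_impact`, the convention of the published
#' difference column (positive when the voxelised program estimates a
#' higher dose).
#'
#' @param table Median dose table ([median_dose_table()]).
#' @param protocol,sex,site Cell selector.  Use `sex = "neutral"`,
#'   `site = "effective_dose"` for the effective-dose row.
#' @return The difference in mSv.
#' @export
dose_difference <- function(table, protocol, sex, site) {
  cell <- table %>%
    dplyr::filter(
      .data$protocol == !!protocol, .data$sex == !!sex, .data$site == !!site
    )
  vals <- setNames(cell$median_msv, cell$software)
  if (!all(c("impact", "ncict") %in% names(vals))) {
    abort(
      paste0(
        "median table has no complete (impact, ncict) pair for (",
        protocol, ", ", sex, ", ", site, ")"
      ),
      class = "ctdoserisk_missing_cell"
    )
  }
  unname(vals[["ncict"]] - vals[["impact"]])
}

#' All pairwise median differences of a dose table
#'
#' @param table Median dose table.
#' @return Tibble `protocol, sex, site, impact_msv, ncict_msv, difference_msv`
#'   with `difference_msv = ncict - impact`.
#' @export
median_differences <- function(table) {
  table %>%
    tidyr::pivot_wider(
      id_cols = c("protocol", "sex", "site", "n_cases"),
      names_from = "software", values_from = "median_msv"
    ) %>%
    dplyr::mutate(
      impact_msv = .data$impact, ncict_msv = .data$ncict,
      difference_msv = .data$ncict - .data$impact
    ) %>%
    dplyr::select(
      "protocol", "sex", "site", "n_cases",
      "impact_msv", "ncict_msv", "difference_msv"
    )
}

#' Read / write a median dose table CSV
#'
#' Columns `protocol, sex, software, site, median_msv, n_cases`.
#'
#' @param path CSV path.
#' @return [read_median_table()]: the tibble; [write_median_table()]:
#'   `path` invisibly.
#' @export
read_median_table <- function(path) {
  tbl <- readr::read_csv(path, show_col_types = FALSE, comment = "#")
  need <- c("protocol", "sex", "software", "site", "median_msv", "n_cases")
  missing <- setdiff(need, names(tbl))
  if (length(missing) > 0) {
    abort(
      paste0("median table CSV is missing columns: ", paste(missing, collapse = ", ")),
      class = "ctdoserisk_schema_error"
    )
  }
  if (any(tbl$median_msv < 0, na.rm = TRUE)) {
    abort("medians must be non-negative", class = "ctdoserisk_domain_error")
  }
  tbl
}

#' @rdname read_median_table
#' @param table Median dose table tibble.
#' @export
write_median_table <- function(table, path) {
  readr::write_csv(table, path)
  invisible(path)
}

#' Published reference median doses
#'
#' The median organ equivalent doses (and gender-neutral effective dose)
#' per protocol, sex and software published by the reference comparison
#' study of adult CT protocols, shipped as a package fixture.
#'
#' @return Long median dose table (see [median_dose_table()]).
#' @export
#' @examples
#' tab <- study_median_doses()
#' dose_difference(tab, "abdomen_pelvis", "male", "stomach")
study_median_doses <- function() {
  study_reference_table() %>%
    tidyr::pivot_longer(
      cols = c("impact_msv", "ncict_msv"),
      names_to = "software", values_to = "median_msv"
    ) %>%
    dplyr::mutate(software = sub("_msv$", "", .data$software)) %>%
    dplyr::select(
      "protocol", "sex", "software", "site", "median_msv", "n_cases"
    )
}

#' @rdname study_median_doses
#' @details `study_reference_table()` returns the wide form including the
#'   study's printed difference column (`printed_difference_msv`), useful
#'   for checking that recomputed differences agree with the published
#'   values to rounding.
#' @export
study_reference_table <- function() {
  path <- system.file("extdata", "reference_medians.csv",
    package = "ctdoserisk", mustWork = TRUE
  )
  readr::read_csv(path, show_col_types = FALSE, comment = "#")
}
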