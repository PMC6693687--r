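# Lifetime attributable risk (LAR) projection.  Median organ equivalent
# doses (mSv, numerically equal to mGy for CT photons) are combined with
# the BEIR VII Table 12D-1 incidence coefficients (cases per 100,000
# persons per 0.1 Gy) by linear interpolation over exposure age, yielding
# per-site and total LAR curves for exposure ages 18-80.

beir_knot_ages <- c(0, 5, 10, 15, 20, 30, 40, 50, 60, 70, 80)

#' Load a risk-coefficient table
#'
#' Accepts the long CSV form `sex,site,age,coefficient` or JSON
#' `{sex: {site: {age: value}}}`.  Units are cases per 100,000 persons per
#' 0.1 Gy (100 mGy).  Validation requires, for every (sex, site) pair
#' present, a complete strictly-increasing age grid shared by the whole
#' table and non-negative coefficients; partial grids are rejected with
#' the offending cell named.
#'
#' @param path Path to the coefficient file.
#' @return Tibble `sex, site, age, coefficient` of class
#'   `risk_coefficients`.
#' @export
load_coefficients <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    raw <- jsonlite::read_json(path, simplifyVector = TRUE)
    tbl <- purrr::imap_dfr(raw, function(sites, sex) {
      purrr::imap_dfr(sites, function(vals, site) {
        tibble::tibble(
          sex = sex, site = site,
          age = as.numeric(names(vals)), coefficient = as.numeric(vals)
        )
      })
    })
  } else {
    tbl <- readr::read_csv(path,
      show_col_types = FALSE, comment = "#",
      col_types = readr::cols(
        sex = readr::col_character(), site = readr::col_character(),
        age = readr::col_double(), coefficient = readr::col_double()
      )
    )
  }
  validate_coefficients(tbl)
}

validate_coefficients <- function(tbl) {
  need <- c("sex", "site", "age", "coefficient")
  missing <- setdiff(need, names(tbl))
  if (length(missing) > 0) {
    abort(
      paste0("coefficient table is missing columns: ", paste(missing, collapse = ", ")),
      class = "ctdoserisk_schema_error"
    )
  }
  bad_site <- setdiff(unique(tbl$site), cancer_sites())
  if (length(bad_site) > 0) {
    abort(
      paste0("unknown cancer site(s) in coefficient table: ", paste(bad_site, collapse = ", ")),
      class = "ctdoserisk_schema_error"
    )
  }
  if (any(!is.finite(tbl$coefficient)) || any(tbl$coefficient < 0)) {
    abort("coefficients must be finite and non-negative",
      class = "ctdoserisk_schema_error"
    )
  }
  ages <- sort(unique(tbl$age))
  if (any(diff(ages) <= 0)) {
    abort("tabulated ages must be strictly increasing",
      class = "ctdoserisk_schema_error"
    )
  }
  full <- tidyr::expand_grid(
    dplyr::distinct(tbl, .data$sex, .data$site), age = ages
  )
  got <- dplyr::distinct(tbl, .data$sex, .data$site, .data$age)
  gap <- dplyr::anti_join(full, got, by = c("sex", "site", "age"))
  if (nrow(gap) > 0) {
    abort(
      paste0(
        "coefficient grid incomplete; first missing cell: (",
        gap$sex[1], ", ", gap$site[1], ", age ", gap$age[1], ")"
      ),
      class = "ctdoserisk_schema_error"
    )
  }
  structure(
    dplyr::arrange(tibble::as_tibble(tbl), .data$sex, .data$site, .data$age),
    class = c("risk_coefficients", class(tibble::tibble()))
  )
}

#' Write a risk-coefficient table
#'
#' @param coefficients Coefficient tibble (see [load_coefficients()]).
#' @param path Output path; `.json` writes the nested JSON form, anything
#'   else the long CSV form.
#' @return `path`, invisibly.
#' @export
write_coefficients <- function(coefficients, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    nested <- split(coefficients, coefficients$sex) %>%
      purrr::map(function(d) {
        split(d, d$site) %>%
          purrr::map(~ setNames(as.list(.x$coefficient), .x$age))
      })
    jsonlite::write_json(nested, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else {
    readr::write_csv(
      coefficients[, c("sex", "site", "age", "coefficient")], path
    )
  }
  invisible(path)
}

#' Vendored BEIR VII incidence coefficients
#'
#' The Table 12D-1 lifetime-attributable-risk-of-incidence coefficients
#' (cases per 100,000 persons exposed to 0.1 Gy) transcribed from the
#' public BEIR VII report for the twelve site categories used here, at the
#' tabulated exposure ages 0, 5, ..., 20, 30, ..., 80.
#'
#' @return Coefficient tibble (see [load_coefficients()]).
#' @export
beir_coefficients <- function() {
  load_coefficients(system.file("extdata", "beir_vii_incidence.csv",
    package = "ctdoserisk", mustWork = TRUE
  ))
}

#' Interpolate a risk coefficient at an arbitrary exposure age
#'
#' Piecewise-linear interpolation between the tabulated knot ages; exact
#' at the knots, no extrapolation outside the grid.
#'
#' @param coefficients Coefficient tibble.
#' @param sex `"male"` or `"female"`.
#' @param site Cancer site.
#' @param age Exposure age(s), inside the tabulated range.
#' @return Interpolated coefficient(s), cases per 100,000 per 0.1 Gy.
#' @export
interpolate_coefficient <- function(coefficients, sex, site, age) {
  rows <- coefficients[coefficients$sex == sex & coefficients$site == site, ]
  if (nrow(rows) == 0) {
    abort(
      paste0("no coefficients for (", sex, ", ", site, ")"),
      class = "ctdoserisk_missing_cell"
    )
  }
  if (any(age < min(rows$age) | age > max(rows$age))) {
    abort(
      paste0(
        "exposure age outside the tabulated range [",
        min(rows$age), ", ", max(rows$age), "]; no extrapolation"
      ),
      class = "ctdoserisk_domain_error"
    )
  }
  approx(rows$age, rows$coefficient, xout = age, method = "linear")$y
}

#' LAR of cancer incidence for a single exposure age
#'
#' Per site: `dose / 100 * coefficient(age)` — the dose in mGy scaled to
#' the coefficient's 0.1 Gy unit.  Sites inapplicable to the given sex are
#' excluded; a dosed site missing from the coefficient table is an error.
#'
#' @param doses Tibble `site, dose_msv` of median organ equivalent doses
#'   for one protocol x sex x software (the `effective_dose` row, if
#'   present, is ignored).
#' @param coefficients Coefficient tibble.
#' @param sex `"male"` or `"female"`.
#' @param age Exposure age.
#' @return Tibble `site, lar_per_100k` plus a `total` attribute; the total
#'   equals the sum over sites.
#' @export
lar_single_exposure <- function(doses, coefficients, sex, age) {
  doses <- doses[doses$site %in% cancer_sites(sex), ]
  missing <- setdiff(
    unique(doses$site),
    unique(coefficients$site[coefficients$sex == sex])
  )
  if (length(missing) > 0) {
    abort(
      paste0(
        "dosed site(s) absent from the coefficient table: ",
        paste(missing, collapse = ", ")
      ),
      class = "ctdoserisk_missing_cell"
    )
  }
  out <- doses %>%
    dplyr::mutate(
      lar_per_100k = .data$dose_msv / 100 *
        purrr::map_dbl(.data$site, ~ interpolate_coefficient(coefficients, sex, .x, age))
    ) %>%
    dplyr::select("site", "lar_per_100k")
  attr(out, "total") <- sum(out$lar_per_100k)
  out
}

#' LAR curve across exposure ages
#'
#' Evaluates [lar_single_exposure()] at every integer age in `ages`
#' (default 18-80), for one protocol x sex x software dose slice.
#'
#' @param doses Tibble `site, dose_msv` (see [lar_single_exposure()]), or
#'   a median dose table from which one slice is selected via `protocol`
#'   and `software`.
#' @param coefficients Coefficient tibble.
#' @param sex `"male"` or `"female"`.
#' @param ages Integer exposure ages, inside the coefficient grid.
#' @param protocol,software Optional slice selectors when `doses` is a
#'   full median dose table.
#' @return Object of class `lar_curve`: tibble `age, site, lar_per_100k`
#'   with attributes `sex`, `protocol`, `software`.  See [lar_total()],
#'   [site_contributions()], [pct_higher_curve()].
#' @export
lar_curve <- function(doses, coefficients, sex, ages = 18:80,
                      protocol = NULL, software = NULL) {
  if (!is.null(protocol) || !is.null(software)) {
    doses <- doses[
      doses$protocol %in% protocol & doses$software %in% software &
        doses$sex == sex,
    ]
  }
  doses <- doses[doses$site != "effective_dose", c("site", "dose_msv", "median_msv")[
    c("site", "dose_msv", "median_msv") %in% names(doses)
  ]]
  if ("median_msv" %in% names(doses) && !"dose_msv" %in% names(doses)) {
    doses <- dplyr::rename(doses, dose_msv = "median_msv")
  }
  if (nrow(doses) == 0) {
    abort("no dose rows selected", class = "ctdoserisk_domain_error")
  }
  curve <- purrr::map_dfr(ages, function(a) {
    dplyr::mutate(lar_single_exposure(doses, coefficients, sex, a), age = a)
  }) %>%
    dplyr::select("age", "site", "lar_per_100k")
  structure(curve,
    sex = sex, protocol = protocol %||% NA_character_,
    software = software %||% NA_character_,
    class = c("lar_curve", class(tibble::tibble()))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Total LAR by exposure age
#'
#' @param curve A [lar_curve()].
#' @return Tibble `age, total` where `total` sums the per-site LAR.
#' @export
lar_total <- function(curve) {
  curve %>%
    dplyr::group_by(.data$age) %>%
    dplyr::summarise(total = sum(.data$lar_per_100k), .groups = "drop")
}

#' Percentage by which the reference curve exceeds the comparison curve
#'
#' Per exposure age: `100 * (total_ncict - total_impact) / total_ncict`,
#' the difference denominated by the reference (voxelised-phantom) total,
#' matching the reference-denominated Bland-Altman convention.  Negative
#' values mean the reference projects fewer cancers.
#'
#' @param curve_ncict,curve_impact [lar_curve()]s on identical age grids
#'   for the same sex and protocol.
#' @return Object of class `lar_disparity`: tibble `age, pct_higher` with
#'   a `summary` attribute `c(min, max, mean)` over the ages.  [glance()]
#'   returns the summary as a one-row tibble.
#' @export
pct_higher_curve <- function(curve_ncict, curve_impact) {
  tn <- lar_total(curve_ncict)
  ti <- lar_total(curve_impact)
  if (!identical(tn$age, ti$age)) {
    abort("curves are on different age grids", class = "ctdoserisk_domain_error")
  }
  if (!identical(attr(curve_ncict, "sex"), attr(curve_impact, "sex"))) {
    abort("curves are for different sexes", class = "ctdoserisk_domain_error")
  }
  if (any(tn$total <= 0)) {
    abort("reference totals must be positive", class = "ctdoserisk_domain_error")
  }
  pct <- 100 * (tn$total - ti$total) / tn$total
  out <- tibble::tibble(age = tn$age, pct_higher = pct)
  structure(out,
    summary = c(min = min(pct), max = max(pct), mean = mean(pct)),
    class = c("lar_disparity", class(tibble::tibble()))
  )
}

#' @method glance lar_disparity
#' @export
glance.lar_disparity <- function(x, ...) {
  s <- attr(x, "summary")
  tibble::tibble(min = s[["min"]], max = s[["max"]], mean = s[["mean"]])
}

#' Per-site share of the lifetime cancer burden
#'
#' Contribution of each site as a percentage of the total number of
#' projected cancers summed across the exposure ages of the curve (a
#' LAR-weighted lifespan average).  `weighting = "yearly_mean"` instead
#' averages the yearly percentage shares without weighting, as a
#' sensitivity variant.
#'
#' @param curve A [lar_curve()].
#' @param weighting `"total"` (default) or `"yearly_mean"`.
#' @return Tibble `site, pct`, sorted decreasing; the shares sum to 100.
#' @export
site_contributions <- function(curve, weighting = c("total", "yearly_mean")) {
  weighting <- match.arg(weighting)
  if (sum(curve$lar_per_100k) <= 0) {
    abort("curve is identically zero; contributions undefined",
      class = "ctdoserisk_degenerate"
    )
  }
  if (weighting == "total") {
    out <- curve %>%
      dplyr::group_by(.data$site) %>%
      dplyr::summarise(lar = sum(.data$lar_per_100k), .groups = "drop") %>%
      dplyr::mutate(pct = 100 * .data$lar / sum(.data$lar)) %>%
      dplyr::select("site", "pct")
  } else {
    out <- curve %>%
      dplyr::group_by(.data$age) %>%
      dplyr::mutate(share = 100 * .data$lar_per_100k / sum(.data$lar_per_100k)) %>%
      dplyr::group_by(.data$site) %>%
      dplyr::summarise(pct = mean(.data$share), .groups = "drop")
  }
  dplyr::arrange(out, dplyr::desc(.data$pct))
}

#' @method autoplot lar_curve
#' @export
autoplot.lar_curve <- function(object, ...) {
  tot <- lar_total(object) %>% dplyr::mutate(site = "total")
  ggplot2::ggplot(
    object, ggplot2::aes(x = .data$age, y = .data$lar_per_100k, colour = .data$site)
  ) +
    ggplot2::geom_line() +
    ggplot2::geom_line(
      data = tot, ggplot2::aes(y = .data$total), colour = "black", linewidth = 1
    ) +
    ggplot2::labs(
      x = "age at exposure (years)",
      y = "LAR of cancer incidence per 100,000",
      title = paste(
        attr(object, "protocol"), attr(object, "sex"),
        attr(object, "software"),
        sep = " / "
      )
    )
}
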