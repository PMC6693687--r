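# Domain vocabulary: CT protocols, BEIR VII cancer-site categories, and the
# organ-label alias table that maps software-specific organ names onto them.

#' CT protocols covered by the comparison
#'
#' @return Character vector of the three protocol identifiers.
#' @export
protocols <- function() {
  c("abdomen_pelvis", "chest", "head")
}

#' BEIR VII cancer-site categories
#'
#' The twelve incidence categories of BEIR VII Table 12D-1 used here.
#' `prostate` is male-specific; `breast`, `uterus` and `ovary` are
#' female-specific.  `other` aggregates the remainder organs and
#' `leukaemia` corresponds to the red/active bone marrow dose.
#'
#' @param sex Optionally restrict to the sites applicable to `"male"` or
#'   `"female"`.  The default `NULL` returns all twelve.
#' @return Character vector of site names.
#' @export
#' @examples
#' cancer_sites("male")
cancer_sites <- function(sex = NULL) {
  all <- c(
    "stomach", "colon", "liver", "lung", "prostate", "uterus", "ovary",
    "bladder", "breast", "thyroid", "other", "leukaemia"
  )
  if (is.null(sex)) {
    return(all)
  }
  sex <- match.arg(sex, c("male", "female"))
  drop <- switch(sex,
    male = c("uterus", "ovary", "breast"),
    female = "prostate"
  )
  setdiff(all, drop)
}

#' Sex-specific cancer sites
#'
#' @return Named list with the sites that only apply to one sex.
#' @export
sex_specific_sites <- function() {
  list(male = "prostate", female = c("breast", "uterus", "ovary"))
}

#' Read an organ-label alias table
#'
#' The alias file is editable JSON with one block per dosimetry program:
#' `labels` maps software organ labels to BEIR VII categories and
#' `remainder_organs` lists the labels whose per-organ medians are averaged
#' into the `other` category.
#'
#' @param path Path to the alias JSON.  Defaults to the table shipped with
#'   the package.
#' @return Nested list: `list(impact = list(labels, remainder_organs), ...)`.
#' @export
read_organ_aliases <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "organ_aliases.json",
      package = "ctdoserisk", mustWork = TRUE
    )
  }
  aliases <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (sw in c("impact", "ncict")) {
    if (is.null(aliases[[sw]]$labels) || is.null(aliases[[sw]]$remainder_organs)) {
      abort(
        paste0("alias table is missing 'labels' or 'remainder_organs' for '", sw, "'"),
        class = "ctdoserisk_schema_error"
      )
    }
    bad <- setdiff(unlist(aliases[[sw]]$labels), cancer_sites())
    if (length(bad) > 0) {
      abort(
        paste0(
          "alias table for '", sw, "' maps to unknown cancer sites: ",
          paste(bad, collapse = ", ")
        ),
        class = "ctdoserisk_schema_error"
      )
    }
  }
  aliases
}

#' Default organ alias table
#'
#' @return The alias table shipped with the package (see
#'   [read_organ_aliases()]).
#' @export
default_organ_aliases <- function() {
  read_organ_aliases(NULL)
}

normalise_label <- function(label) {
  tolower(trimws(label))
}

#' Map a software organ label to its BEIR VII category
#'
#' Matching is case-insensitive and whitespace-trimmed.  Labels listed as
#' remainder organs map to `"other"`; e.g. `"Bone Marrow"` (first program)
#' and `"active marrow"` (second program) both map to `"leukaemia"`.
#'
#' @param label Organ label(s) as emitted by the dosimetry program.
#' @param software `"impact"` or `"ncict"`.
#' @param aliases Alias table from [read_organ_aliases()].
#' @return Character vector of cancer sites, same length as `label`.
#' @export
#' @examples
#' map_organ_label("Bone Marrow", "impact")
#' map_organ_label("active marrow", "ncict")
map_organ_label <- function(label, software, aliases = default_organ_aliases()) {
  software <- match.arg(software, c("impact", "ncict"))
  block <- aliases[[software]]
  labels <- block$labels
  names(labels) <- normalise_label(names(labels))
  remainder <- normalise_label(unlist(block$remainder_organs))
  key <- normalise_label(label)
  out <- character(length(key))
  for (i in seq_along(key)) {
    if (key[i] %in% names(labels)) {
      out[i] <- labels[[key[i]]]
    } else if (key[i] %in% remainder) {
      out[i] <- "other"
    } else {
      abort(
        paste0(
          "unmapped organ label '", label[i], "' for software '", software, "'"
        ),
        class = "ctdoserisk_unmapped_label"
      )
    }
  }
  out
}

#' Aggregate remainder-organ medians into the `other` category
#'
#' The `other` BEIR VII category is not reported by either dosimetry
#' program; it is the arithmetic mean of the median doses of the remainder
#' organs, which assumes each remainder organ contributes equally to risk.
#'
#' @param remainder_medians Non-empty numeric vector of per-organ median
#'   doses (mSv), all non-negative.
#' @return The mean dose (mSv).
#' @export
compute_other_dose <- function(remainder_medians) {
  if (length(remainder_medians) == 0) {
    abort("remainder_medians must be non-empty", class = "ctdoserisk_domain_error")
  }
  if (any(!is.finite(remainder_medians)) || any(remainder_medians < 0)) {
    abort("remainder_medians must be finite and non-negative",
      class = "ctdoserisk_domain_error"
    )
  }
  mean(remainder_medians)
}

#' Average the sex-specific effective doses
#'
#' The voxelised-phantom program reports sex-specific effective dose; for
#' comparison with the hermaphrodite-phantom result the male and female
#' values are averaged.
#'
#' @param e_male,e_female Effective doses (mSv), non-negative; vectorised.
#' @return Elementwise arithmetic mean (mSv).
#' @export
average_effective_dose <- function(e_male, e_female) {
  if (any(e_male < 0, na.rm = TRUE) || any(e_female < 0, na.rm = TRUE)) {
    abort("effective doses must be non-negative", class = "ctdoserisk_domain_error")
  }
  (e_male + e_female) / 2
}
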