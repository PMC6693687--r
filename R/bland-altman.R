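# Reference-denominated Bland-Altman agreement analysis.  Because the
# between-method differences scale with dose magnitude, differences are
# expressed as a percentage of the voxelised-phantom (reference) result
# rather than as raw differences against the pairwise mean.

#' Percentage difference relative to the reference result
#'
#' `100 * (ncict - impact) / ncict`: positive when the reference
#' (voxelised-phantom) value is the larger, negative when it falls below
#' the line of equivalence.
#'
#' @param impact_value,ncict_value Paired dose values (mSv); vectorised.
#'   The reference (`ncict_value`) must be strictly positive.
#' @return Percentage difference(s).
#' @export
#' @examples
#' pct_difference(12.00, 6.31) # about -90%
pct_difference <- function(impact_value, ncict_value) {
  if (any(ncict_value <= 0, na.rm = TRUE)) {
    abort("reference values must be strictly positive",
      class = "ctdoserisk_domain_error"
    )
  }
  100 * (ncict_value - impact_value) / ncict_value
}

#' Bland-Altman agreement analysis against a reference method
#'
#' Plots each pair at the reference (voxelised-phantom) value on the
#' horizontal axis and the percentage difference on the vertical axis;
#' the bias is the mean percentage difference and the limits of agreement
#' are mean +/- 1.96 standard deviations (n - 1 denominator).
#'
#' @param data Data frame of paired values.
#' @param impact,ncict Columns with the two methods' values (tidy
#'   evaluation); `ncict` is the reference.
#' @param reference_label Axis label for the reference method.
#' @return Object of class `bland_altman` with `points` (tibble
#'   `reference_value, pct_difference`), `mean_pct_difference` and
#'   `limits_of_agreement`.  Supports [tidy()], [glance()], [autoplot()].
#' @export
bland_altman <- function(data, impact, ncict, reference_label = "NCICT") {
  iv <- as.numeric(dplyr::pull(data, {{ impact }}))
  nv <- as.numeric(dplyr::pull(data, {{ ncict }}))
  if (length(iv) < 2) {
    abort("Bland-Altman analysis needs at least 2 pairs",
      class = "ctdoserisk_degenerate"
    )
  }
  pct <- pct_difference(iv, nv)
  m <- mean(pct)
  s <- sd(pct)
  structure(
    list(
      points = tibble::tibble(reference_value = nv, pct_difference = pct),
      mean_pct_difference = m,
      limits_of_agreement = c(lower = m - 1.96 * s, upper = m + 1.96 * s),
      reference_label = reference_label
    ),
    class = "bland_altman"
  )
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf(
    "Bland-Altman (%% of %s, n = %d): bias %.2f%%, limits (%.2f%%, %.2f%%)\n",
    x$reference_label, nrow(x$points), x$mean_pct_difference,
    x$limits_of_agreement[["lower"]], x$limits_of_agreement[["upper"]]
  ))
  invisible(x)
}

#' @method tidy bland_altman
#' @export
tidy.bland_altman <- function(x, ...) {
  x$points
}

#' @method glance bland_altman
#' @export
glance.bland_altman <- function(x, ...) {
  tibble::tibble(
    n = nrow(x$points),
    mean_pct_difference = x$mean_pct_difference,
    loa_lower = x$limits_of_agreement[["lower"]],
    loa_upper = x$limits_of_agreement[["upper"]]
  )
}

#' @method autoplot bland_altman
#' @export
autoplot.bland_altman <- function(object, ...) {
  ggplot2::ggplot(
    object$points,
    ggplot2::aes(x = .data$reference_value, y = .data$pct_difference)
  ) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey40") +
    ggplot2::geom_hline(
      yintercept = object$mean_pct_difference, linetype = "dashed"
    ) +
    ggplot2::geom_hline(
      yintercept = object$limits_of_agreement, linetype = "dotted"
    ) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(
      x = paste0(object$reference_label, " (reference, mSv)"),
      y = paste0("difference (% of ", object$reference_label, ")")
    )
}
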