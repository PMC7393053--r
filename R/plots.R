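#' Plot spectra, optionally averaged by class
#'
#' @param spectra A spectra tibble.
#' @param by_label Average replicate spectra within each class label?
#' @return A ggplot of absorbance vs wavenumber (axis reversed, the
#'   infrared convention).
#' @export
plot_spectra <- function(spectra, by_label = TRUE) {
  long <- spec_longer(spectra)
  if (by_label && "label" %in% names(long)) {
    long <- dplyr::summarise(
      dplyr::group_by(long, .data$label, .data$wavenumber),
      absorbance = mean(.data$absorbance), .groups = "drop"
    )
    long$grp <- long$label
  } else {
    long$grp <- long$sample_id
  }
  ggplot2::ggplot(
    long,
    ggplot2::aes(.data$wavenumber, .data$absorbance,
      group = .data$grp,
      colour = if ("label" %in% names(long)) .data$label else NULL
    )
  ) +
    ggplot2::geom_line() +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(
      x = expression(wavenumber ~ (cm^-1)), y = "absorbance (AU)",
      colour = NULL
    ) +
    ggplot2::theme_minimal()
}
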