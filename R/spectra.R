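#' Build a wavenumber grid
#'
#' ATR-FTIR spectra are recorded from high to low wavenumber; the grid is a
#' strictly decreasing sequence in cm^-1. The default covers the full
#' mid-infrared acquisition range 4000-400 cm^-1 with 2 cm^-1 point spacing
#' (a 4 cm^-1 instrument resolution is conventionally digitized at half the
#' resolution).
#'
#' @param start Highest wavenumber, cm^-1.
#' @param end Lowest wavenumber, cm^-1. Must satisfy `start > end`.
#' @param step Point spacing, cm^-1 (> 0).
#' @return Numeric vector of wavenumbers, strictly decreasing, length
#'   `floor((start - end) / step) + 1`.
#' @examples
#' length(wavenumber_grid()) # 1801
#' @export
wavenumber_grid <- function(start = 4000, end = 400, step = 2) {
  stopifnot(is.numeric(start), is.numeric(end), is.numeric(step))
  if (start <= end) stop("`start` must exceed `end` (grid is decreasing)")
  if (step <= 0) stop("`step` must be positive")
  seq(start, by = -step, length.out = floor((start - end) / step) + 1)
}

# Metadata columns every spectra tibble carries, in canonical order.
spec_meta_cols <- c("sample_id", "label", "soy_fraction", "split")

is_spectral_name <- function(x) {
  grepl("^-?[0-9]+(\\.[0-9]+)?$", x)
}

#' Wavenumber axis of a spectra tibble
#'
#' Spectral columns are named by their wavenumber (e.g. `"1700"`), so the
#' axis survives dplyr/tidyr manipulation of the metadata columns.
#'
#' @param spectra A spectra tibble (see [as_spectra()]).
#' @return Numeric vector of wavenumbers in column order.
#' @export
spec_wavenumbers <- function(spectra) {
  as.numeric(names(spectra)[is_spectral_name(names(spectra))])
}

#' Absorbance matrix of a spectra tibble
#'
#' @param spectra A spectra tibble.
#' @return Numeric matrix, samples in rows (named by `sample_id`),
#'   wavenumbers in columns.
#' @export
spec_matrix <- function(spectra) {
  cols <- names(spectra)[is_spectral_name(names(spectra))]
  if (length(cols) == 0) stop("no spectral columns found")
  m <- as.matrix(spectra[, cols])
  storage.mode(m) <- "double"
  if ("sample_id" %in% names(spectra)) rownames(m) <- spectra$sample_id
  m
}

#' Metadata columns of a spectra tibble
#'
#' @param spectra A spectra tibble.
#' @return Tibble with the per-sample metadata (`sample_id`, `label`,
#'   `soy_fraction`, `split`) that are present.
#' @export
spec_meta <- function(spectra) {
  out <- spectra[, intersect(spec_meta_cols, names(spectra)), drop = FALSE]
  # a bare metadata table; fitted-state attributes do not ride along
  attr(out, "preprocess_model") <- NULL
  attr(out, "feature_stats") <- NULL
  tibble::as_tibble(out)
}

#' Assemble a spectra tibble from a matrix and metadata
#'
#' The spectra tibble is the unit all pipeline stages exchange: one row per
#' sample, metadata columns first, then one numeric column per grid point
#' named by its wavenumber.
#'
#' @param absorbance Numeric matrix, samples x wavenumbers (a single
#'   spectrum may be given as a vector).
#' @param wavenumbers Numeric axis, one per matrix column.
#' @param meta Optional data frame of per-sample metadata; recycled columns
#'   `sample_id`, `label`, `soy_fraction`, `split` are kept in canonical
#'   order.
#' @return A spectra tibble.
#' @export
as_spectra <- function(absorbance, wavenumbers, meta = NULL) {
  if (is.vector(absorbance)) absorbance <- matrix(absorbance, nrow = 1)
  stopifnot(ncol(absorbance) == length(wavenumbers))
  if (anyDuplicated(wavenumbers)) stop("duplicate wavenumbers")
  spec <- tibble::as_tibble(absorbance, .name_repair = "minimal")
  names(spec) <- format(wavenumbers, trim = TRUE, scientific = FALSE)
  if (is.null(meta)) {
    meta <- tibble::tibble(sample_id = sprintf("s%03d", seq_len(nrow(absorbance))))
  }
  meta <- tibble::as_tibble(meta)
  stopifnot(nrow(meta) == nrow(spec))
  keep <- intersect(spec_meta_cols, names(meta))
  dplyr::bind_cols(meta[, keep, drop = FALSE], spec)
}

# Replace the spectral block of a spectra tibble, optionally on a new axis.
spec_set_matrix <- function(spectra, m, wavenumbers = NULL) {
  if (is.null(wavenumbers)) wavenumbers <- spec_wavenumbers(spectra)
  as_spectra(m, wavenumbers, meta = spec_meta(spectra))
}

#' Pivot a spectra tibble to long format
#'
#' Convenience for ggplot2: one row per (sample, wavenumber).
#'
#' @param spectra A spectra tibble.
#' @return Tibble with metadata columns plus `wavenumber` and `absorbance`.
#' @export
spec_longer <- function(spectra) {
  cols <- names(spectra)[is_spectral_name(names(spectra))]
  tidyr::pivot_longer(spectra, dplyr::all_of(cols),
    names_to = "wavenumber", values_to = "absorbance",
    names_transform = list(wavenumber = as.numeric)
  )
}
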