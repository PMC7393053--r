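#' Write a spectra set to wide CSV
#'
#' The interchange layout: first column `wavenumber_cm-1`, one column per
#' sample named by `sample_id`. Per-sample metadata go to a companion CSV
#' (`sample_id`, `label`, `soy_fraction_pct`, `split`).
#'
#' @param spectra A spectra tibble.
#' @param path Output CSV path.
#' @param meta_path Companion metadata CSV path; default replaces the
#'   extension with `_meta.csv`. `NULL` skips metadata.
#' @return `path`, invisibly.
#' @export
write_spectra_csv <- function(spectra, path,
                              meta_path = sub("\\.csv$", "_meta.csv", path)) {
  m <- spec_matrix(spectra)
  wide <- dplyr::bind_cols(
    tibble::tibble(`wavenumber_cm-1` = spec_wavenumbers(spectra)),
    tibble::as_tibble(t(m), .name_repair = "minimal")
  )
  # %.17g guarantees bit-exact round-trip of doubles through text
  wide <- dplyr::mutate(wide, dplyr::across(
    dplyr::everything(), ~ sprintf("%.17g", .x)
  ))
  readr::write_csv(wide, path)
  if (!is.null(meta_path)) {
    meta <- spec_meta(spectra)
    names(meta)[names(meta) == "soy_fraction"] <- "soy_fraction_pct"
    readr::write_csv(meta, meta_path)
  }
  invisible(path)
}

#' Read a spectra set from wide CSV
#'
#' Accepts an ascending or descending wavenumber axis (normalized to
#' descending, the instrument convention). Fails loudly on non-numeric
#' cells or duplicate wavenumbers, naming the offending column or row.
#'
#' @param path Wide CSV (first column the wavenumber axis).
#' @param meta_path Optional metadata CSV with a `sample_id` column.
#' @return A spectra tibble.
#' @export
read_spectra_csv <- function(path, meta_path = NULL) {
  # base strtod parsing: bit-exact round trip of %.17g-formatted doubles
  wide <- utils::read.csv(path, check.names = FALSE)
  if (ncol(wide) < 2) stop("no sample columns in ", path)
  for (j in seq_len(ncol(wide))) {
    if (!is.numeric(wide[[j]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(wide[[j]]))))[1]
      stop(
        "non-numeric cell in column '", names(wide)[j], "'",
        if (!is.na(bad)) paste0(", row ", bad) else ""
      )
    }
  }
  w <- wide[[1]]
  if (anyDuplicated(w)) {
    stop("duplicate wavenumber at row ", which(duplicated(w))[1])
  }
  d <- diff(w)
  if (!all(d > 0) && !all(d < 0)) stop("wavenumber axis is not monotone")
  ord <- order(w, decreasing = TRUE)
  m <- t(as.matrix(wide[ord, -1, drop = FALSE]))
  meta <- tibble::tibble(sample_id = names(wide)[-1])
  if (!is.null(meta_path)) {
    md <- readr::read_csv(meta_path, show_col_types = FALSE)
    names(md)[names(md) == "soy_fraction_pct"] <- "soy_fraction"
    meta <- dplyr::left_join(meta, md, by = "sample_id")
  }
  as_spectra(m, w[ord], meta = meta)
}

#' Read a JCAMP-DX infrared spectrum
#'
#' Minimal reader for single-spectrum JCAMP-DX files with an
#' `##XYDATA=(X++(Y..Y))` or `##XYPOINTS=(XY..XY)` block. Y units must be
#' ABSORBANCE; TRANSMITTANCE is accepted only with
#' `convert_transmittance = TRUE`, applying `A = -log10(T)`.
#'
#' @param path JCAMP-DX file.
#' @param convert_transmittance Convert transmittance data to absorbance?
#' @return A one-row spectra tibble on the file's grid (descending).
#' @export
read_jcamp <- function(path, convert_transmittance = FALSE) {
  lines <- readLines(path, warn = FALSE)
  if (!any(grepl("^##END=", lines))) stop("truncated JCAMP file (no ##END=)")
  get_field <- function(key) {
    hit <- grep(paste0("^##", key, "="), lines, value = TRUE)
    if (length(hit) == 0) return(NULL)
    trimws(sub(paste0("^##", key, "="), "", hit[1]))
  }
  yunits <- toupper(get_field("YUNITS") %||% "")
  transmittance <- grepl("TRANSMITTANCE", yunits)
  if (!grepl("ABSORBANCE", yunits) && !transmittance) {
    stop("unsupported YUNITS '", yunits, "' (need ABSORBANCE or TRANSMITTANCE)")
  }
  if (transmittance && !convert_transmittance) {
    stop("file is in transmittance; pass convert_transmittance = TRUE")
  }
  xfactor <- as.numeric(get_field("XFACTOR") %||% "1")
  yfactor <- as.numeric(get_field("YFACTOR") %||% "1")

  start_xy <- grep("^##(XYDATA|XYPOINTS)=", lines)
  if (length(start_xy) == 0) stop("no ##XYDATA or ##XYPOINTS block")
  is_points <- grepl("^##XYPOINTS=", lines[start_xy[1]])
  end <- grep("^##", lines)
  end <- min(end[end > start_xy[1]]) - 1
  body <- lines[(start_xy[1] + 1):end]
  body <- body[nzchar(trimws(body))]
  if (length(body) == 0) stop("empty data block")

  if (is_points) {
    tok <- as.numeric(unlist(strsplit(trimws(body), "[,;[:space:]]+")))
    if (anyNA(tok) || length(tok) %% 2 != 0) stop("malformed XYPOINTS record")
    x <- tok[seq(1, length(tok), 2)] * xfactor
    y <- tok[seq(2, length(tok), 2)] * yfactor
  } else {
    x <- numeric(0)
    y <- numeric(0)
    for (ln in body) {
      tok <- as.numeric(strsplit(trimws(ln), "[[:space:]]+")[[1]])
      if (anyNA(tok) || length(tok) < 2) stop("malformed XYDATA line: ", ln)
      x0 <- tok[1] * xfactor
      ys <- tok[-1] * yfactor
      npts <- as.numeric(get_field("NPOINTS") %||% NA)
      firstx <- as.numeric(get_field("FIRSTX") %||% NA)
      lastx <- as.numeric(get_field("LASTX") %||% NA)
      step <- if (!is.na(npts) && !is.na(firstx) && !is.na(lastx) && npts > 1) {
        (lastx - firstx) / (npts - 1)
      } else {
        NA_real_
      }
      if (is.na(step)) stop("XYDATA needs FIRSTX, LASTX and NPOINTS")
      x <- c(x, x0 + step * (seq_along(ys) - 1))
      y <- c(y, ys)
    }
    npts <- as.numeric(get_field("NPOINTS"))
    if (length(y) != npts) {
      stop("XYDATA has ", length(y), " points but NPOINTS=", npts)
    }
  }
  if (transmittance) {
    if (any(y <= 0)) stop("nonpositive transmittance cannot be converted")
    y <- -log10(y)
  }
  ord <- order(x, decreasing = TRUE)
  title <- get_field("TITLE") %||% "jcamp"
  as_spectra(y[ord], x[ord], meta = tibble::tibble(sample_id = title))
}

#' Write one spectrum as JCAMP-DX
#'
#' Emits a minimal `##XYDATA=(X++(Y..Y))` absorbance record on the
#' spectrum's own grid.
#'
#' @param spectrum A one-row spectra tibble.
#' @param path Output file.
#' @param title `##TITLE=` field.
#' @return `path`, invisibly.
#' @export
write_jcamp <- function(spectrum, path, title = spectrum$sample_id[1]) {
  w <- spec_wavenumbers(spectrum)
  y <- spec_matrix(spectrum)[1, ]
  per_line <- 6
  rows <- split(seq_along(y), ceiling(seq_along(y) / per_line))
  data_lines <- vapply(rows, function(i) {
    paste(
      format(w[i[1]], trim = TRUE, scientific = FALSE),
      paste(format(y[i], trim = TRUE, digits = 10), collapse = " ")
    )
  }, character(1))
  writeLines(c(
    paste0("##TITLE=", title),
    "##JCAMP-DX=4.24",
    "##DATA TYPE=INFRARED SPECTRUM",
    "##XUNITS=1/CM",
    "##YUNITS=ABSORBANCE",
    "##XFACTOR=1",
    "##YFACTOR=1",
    paste0("##FIRSTX=", format(w[1], trim = TRUE, scientific = FALSE)),
    paste0("##LASTX=", format(w[length(w)], trim = TRUE, scientific = FALSE)),
    paste0("##NPOINTS=", length(y)),
    "##XYDATA=(X++(Y..Y))",
    data_lines,
    "##END="
  ), path)
  invisible(path)
}
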