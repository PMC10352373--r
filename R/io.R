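#' Write a 2D result to 32-bit float TIFF with a JSON sidecar
#'
#' Accepts a `scan_image`, `ri_field`, `fluence_map` (cells tallied) or
#' plain matrix; the matrix is written as 32-bit float TIFF and the
#' physical metadata (pitch, axes, seed, generator parameters) to
#' `<path>.json`.
#'
#' @param x Object to write.
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_tiff32 <- function(x, path) {
  if (inherits(x, "scan_image")) {
    m <- x$signal; meta <- c(list(step = x$step), x$meta)
  } else if (inherits(x, "ri_field")) {
    m <- x$values
    meta <- list(dx = x$dx, dz = x$dz, origin = x$origin,
                 cavity = unclass(x$cavity))
  } else if (inherits(x, "fluence_map")) {
    if (is.null(x$cells)) abort("Fluence map was run without `tally_fluence`.")
    m <- x$cells
    meta <- list(cell = x$cell, seed = x$seed, source = unclass(x$source))
  } else if (is.matrix(x)) {
    m <- x; meta <- list()
  } else {
    abort("Unsupported object for TIFF export.")
  }
  rng <- range(m)
  scaled <- if (diff(rng) > 0) (m - rng[1]) / diff(rng) else m * 0
  tiff::writeTIFF(matrix(as.numeric(scaled), nrow(m), ncol(m)),
                  path, bits.per.sample = 32L, reduce = FALSE)
  jsonlite::write_json(c(meta, list(range = rng)),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a 32-bit TIFF written by [write_tiff32()]
#'
#' Values are restored to their physical range using the sidecar.
#'
#' @param path TIFF path.
#' @return A list with the `matrix` and the sidecar `meta` (if present).
#' @export
read_tiff32 <- function(path) {
  m <- tiff::readTIFF(path)
  side <- paste0(path, ".json")
  meta <- if (file.exists(side)) jsonlite::read_json(side, simplifyVector = TRUE)
  if (!is.null(meta$range) && diff(range(meta$range)) > 0) {
    m <- m * diff(meta$range) + meta$range[1]
  }
  list(matrix = m, meta = meta)
}

#' Export a profile or metric table to CSV
#'
#' @param x A `profile1d`, `mtf_curve` or data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_metrics_csv <- function(x, path) {
  df <- if (is.data.frame(x)) x else as.data.frame(x)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
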