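#' DEXA image container
#'
#' A `dexa_image` wraps a 2D grid of non-negative intensities with its pixel
#' spacing and an identifier. Intensities are stored as loaded; phantom
#' images and PNG round-trips use the 0-1 range. Row 1 is superior and
#' increasing column is anterior.
#'
#' @param pixels numeric matrix of intensities, at least 64 rows x 32 columns.
#' @param spacing_mm physical size of one (isotropic) pixel in millimetres.
#' @param id opaque image identifier.
#' @return An object of class `dexa_image` with elements `pixels`,
#'   `spacing_mm` and `id`.
#' @examples
#' img <- dexa_image(matrix(0.1, 80, 40), spacing_mm = 1, id = "example")
#' dim(img$pixels)
#' @export
dexa_image <- function(pixels, spacing_mm = 1, id = "image") {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    abort_aac("pixels must be a numeric matrix", "aac_validation_error")
  if (nrow(pixels) < 64 || ncol(pixels) < 32)
    abort_aac("image grid must have at least 64 rows and 32 columns",
              "aac_config_error")
  if (any(!is.finite(pixels)) || any(pixels < 0))
    abort_aac("all intensities must be finite and non-negative",
              "aac_validation_error")
  if (!is.numeric(spacing_mm) || length(spacing_mm) != 1L || spacing_mm <= 0)
    abort_aac("spacing_mm must be a single positive number",
              "aac_validation_error")
  structure(list(pixels = pixels, spacing_mm = spacing_mm,
                 id = as.character(id)),
            class = "dexa_image")
}

#' @export
print.dexa_image <- function(x, ...) {
  cat(sprintf("<dexa_image> %s: %d x %d px, %.3g mm/px, range [%.3g, %.3g]\n",
              x$id, nrow(x$pixels), ncol(x$pixels), x$spacing_mm,
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' Read and write DEXA images
#'
#' TIFF files are written 16-bit, PNG 8-bit, both with intensities clipped
#' to 0-1; reading normalizes to 0-1 whatever the stored bit depth (the
#' convention the whole pipeline assumes).
#'
#' @param image a [dexa_image].
#' @param path file path ending in `.png`, `.tif` or `.tiff`.
#' @param spacing_mm pixel spacing to attach on read (not stored in PNG).
#' @param id identifier to attach on read; default is the file name.
#' @return `write_dexa` returns `path` invisibly; `read_dexa` a [dexa_image].
#' @export
write_dexa <- function(image, path) {
  stopifnot(inherits(image, "dexa_image"))
  px <- pmin(pmax(image$pixels, 0), 1)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    ## png stores images row-major top-to-bottom, matching our row 1 =
    ## superior convention directly
    png::writePNG(px, target = path, dpi = 25.4 / image$spacing_mm)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(px, path, bits.per.sample = 16L)
  } else {
    abort_aac("unsupported image format: use .png or .tif", "aac_config_error")
  }
  invisible(path)
}

#' @rdname write_dexa
#' @export
read_dexa <- function(path, spacing_mm = 1, id = NULL) {
  ext <- tolower(tools::file_ext(path))
  px <- if (ext == "png") {
    png::readPNG(path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::readTIFF(path)
  } else {
    abort_aac("unsupported image format: use .png or .tif", "aac_config_error")
  }
  if (length(dim(px)) == 3L) px <- px[, , 1L]  # collapse grey stored as RGB
  rng <- range(px)
  if (rng[2] > 1) px <- px / rng[2]            # arbitrary bit depth -> 0-1
  dexa_image(px, spacing_mm = spacing_mm,
             id = if (is.null(id)) tools::file_path_sans_ext(basename(path))
                  else id)
}
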