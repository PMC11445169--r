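#' Droplet image container
#'
#' A square single-channel intensity grid centred on one droplet, with the
#' droplet radius as metadata. Pixel values live on the 16-bit range
#' `[0, 65535]` on disk; in memory they may be held in wider (floating
#' point) arithmetic during filtering.
#'
#' @param pixels Square numeric matrix.
#' @param droplet_radius Droplet radius in pixels (`<= side / 2`); defaults
#'   to `side / 2 - 2`, the convention of crops made at droplet diameter.
#' @param center Optional `(row, col)` centre in 1-based pixel
#'   coordinates; defaults to the geometric image centre.
#' @return An object of class `"droplet_image"` with fields `pixels`,
#'   `side`, `droplet_radius`, `center`.
#' @export
droplet_image <- function(pixels, droplet_radius = NULL, center = NULL) {
  stopifnot(is.matrix(pixels), is.numeric(pixels))
  side <- nrow(pixels)
  if (ncol(pixels) != side)
    stop("droplet_image() requires a square pixel matrix")
  if (is.null(droplet_radius)) droplet_radius <- side / 2 - 2
  stopifnot(droplet_radius > 0, droplet_radius <= side / 2)
  if (is.null(center)) center <- c((side + 1) / 2, (side + 1) / 2)
  structure(list(pixels = pixels, side = side,
                 droplet_radius = droplet_radius, center = center),
            class = "droplet_image")
}

#' @export
print.droplet_image <- function(x, ...) {
  cat(sprintf("<droplet_image %dx%d, radius %.1f px, range [%g, %g]>\n",
              x$side, x$side, x$droplet_radius,
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' Read a single-channel droplet TIFF
#'
#' Reads a grayscale TIFF into a [droplet_image] on the 16-bit scale.
#' 8-bit inputs are rescaled by 257 (so 255 maps to 65535) with a message;
#' non-square inputs are centre-cropped to square with a warning.
#' Multi-channel (RGB) files are a format error: every lossy conversion is
#' either rejected or announced.
#'
#' @param path Path to a TIFF file.
#' @param droplet_radius Optional radius metadata; defaults as in
#'   [droplet_image()].
#' @return A [droplet_image].
#' @export
read_droplet_tiff <- function(path, droplet_radius = NULL) {
  if (!file.exists(path)) stop("read_droplet_tiff(): file not found: ", path)
  px <- tiff::readTIFF(path, as.is = TRUE, info = TRUE)
  if (length(dim(px)) == 3L)
    stop("read_droplet_tiff(): multi-channel TIFF not supported (",
         dim(px)[3], " channels): ", path)
  bits <- attr(px, "bits.per.sample")
  px <- matrix(as.numeric(px), nrow(px), ncol(px))
  if (!is.null(bits) && bits == 8L) {
    message("read_droplet_tiff(): 8-bit input rescaled x257 to 16-bit range")
    px <- px * 257
  }
  if (nrow(px) != ncol(px)) {
    warning("read_droplet_tiff(): non-square image centre-cropped to square")
    side <- min(dim(px))
    r0 <- floor((nrow(px) - side) / 2)
    c0 <- floor((ncol(px) - side) / 2)
    px <- px[(r0 + 1):(r0 + side), (c0 + 1):(c0 + side)]
  }
  droplet_image(px, droplet_radius = droplet_radius)
}

#' Write a droplet image as an uncompressed 16-bit grayscale TIFF
#'
#' @param image A [droplet_image] or numeric matrix; values are clipped to
#'   `[0, 65535]` and rounded to integer counts.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_droplet_tiff <- function(image, path) {
  px <- as_image_matrix(image)
  px <- round(pmin(pmax(px, 0), 65535))
  ok <- try(tiff::writeTIFF(px / 65535, path, bits.per.sample = 16L,
                            compression = "none"), silent = TRUE)
  if (inherits(ok, "try-error"))
    stop("write_droplet_tiff(): cannot write ", path)
  invisible(path)
}

#' Read a dataset manifest
#'
#' Reads a CSV manifest with at least the columns `file` and `label`
#' (`0` = Empty, `1` = Single, `2` = Multiple). Labels outside `{0, 1, 2}`
#' are a validation error that names the offending rows. File paths are
#' resolved relative to the manifest location and returned in a `path`
#' column.
#'
#' @param path Path to a manifest CSV.
#' @return A data.frame with the manifest columns plus resolved `path`.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("read_manifest(): file not found: ", path)
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("file", "label")
  miss <- setdiff(req, names(m))
  if (length(miss))
    stop("read_manifest(): missing required column(s): ",
         paste(miss, collapse = ", "))
  if (nrow(m)) {
    bad <- which(!(m$label %in% 0:2))
    if (length(bad))
      stop("read_manifest(): invalid label(s) ",
           paste(unique(m$label[bad]), collapse = ", "),
           " in row(s) ", paste(bad, collapse = ", "),
           "; labels must be 0 (Empty), 1 (Single) or 2 (Multiple)")
    m$label <- as.integer(m$label)
    m$path <- file.path(dirname(path), m$file)
  } else {
    m$path <- character(0)
  }
  m
}

#' Write a dataset manifest
#'
#' @param records Data.frame with at least `file` and `label` columns.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(records, path) {
  stopifnot(is.data.frame(records), all(c("file", "label") %in% names(records)))
  records$path <- NULL
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Load the images of a manifest
#'
#' @param manifest A data.frame from [read_manifest()].
#' @return A list of [droplet_image] objects, in manifest row order.
#' @export
load_manifest_images <- function(manifest) {
  lapply(manifest$path, read_droplet_tiff)
}
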