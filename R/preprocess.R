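#' Preprocessing configuration
#'
#' Bundles every constant of the beadline-suppressing preprocessing
#' pipeline. The defaults reproduce the published recipe: the bisigmoidal
#' contrast filter divides its exponent argument by 600 and caps it at
#' +/-700 (just below the overflow threshold of `exp()` in double
#' precision), scales the output by 24000, images are resized to 55 x 55
#' pixels, and the circular mask radius is the image half-width reduced by
#' 5 pixels.
#'
#' @param sigmoid_divisor Intensity divisor of the bisigmoid exponent
#'   arguments. Must be positive.
#' @param sigmoid_cap Symmetric clamp on the exponent arguments
#'   (dimensionless). Must be positive.
#' @param sigmoid_scale Output scale of the bisigmoid filter (intensity
#'   counts); half the peak-to-peak output range.
#' @param target_side Side length in pixels of the preprocessed image.
#' @param mask_reduction Pixels subtracted from the image half-width to get
#'   the circular mask radius; must satisfy
#'   `0 <= mask_reduction < target_side / 2`.
#' @param norm_max Upper bound of the affine intensity normalization
#'   (65535 for the native 16-bit range).
#' @param mode `"full"` for the complete pipeline (Prewitt convolution,
#'   bisigmoid, resize, normalize, mask) or `"minimal"` for the control
#'   variant (resize and normalize only).
#'
#' @return A list of class `"preprocess_config"`.
#' @export
#' @examples
#' cfg <- preprocess_config()
#' cfg$target_side
preprocess_config <- function(sigmoid_divisor = 600,
                              sigmoid_cap = 700,
                              sigmoid_scale = 24000,
                              target_side = 55,
                              mask_reduction = 5,
                              norm_max = 65535,
                              mode = c("full", "minimal")) {
  mode <- match.arg(mode)
  stopifnot(sigmoid_divisor > 0, sigmoid_cap > 0, target_side >= 8,
            mask_reduction >= 0, mask_reduction < target_side / 2,
            norm_max > 0)
  structure(list(sigmoid_divisor = sigmoid_divisor,
                 sigmoid_cap = sigmoid_cap,
                 sigmoid_scale = sigmoid_scale,
                 target_side = as.integer(target_side),
                 mask_reduction = mask_reduction,
                 norm_max = norm_max,
                 mode = mode),
            class = "preprocess_config")
}

#' Horizontal-edge Prewitt convolution
#'
#' Convolves an image with the 3 x 3 horizontal-edge Prewitt kernel
#' (rows `+1 +1 +1; 0 0 0; -1 -1 -1`). The response is exactly zero
#' wherever the input is constant along the vertical (row) axis in a 3 x 3
#' neighbourhood -- this is the property that deletes the beadline, an
#' ideal column-constant stripe. Horizontal edges map to large responses of
#' opposite sign above and below the edge (the operator is antisymmetric in
#' the row direction). The border is handled by zero padding so that the
#' output has the same size as the input.
#'
#' @param image Numeric matrix, at least 3 x 3.
#' @return Signed numeric matrix of the same dimensions.
#' @export
#' @examples
#' prewitt_horizontal(matrix(5, 4, 4))       # all zeros
#' step <- rbind(matrix(0, 3, 5), matrix(10, 3, 5))
#' prewitt_horizontal(step)[3:4, 3]          # +/- 30 straddling the step
prewitt_horizontal <- function(image) {
  image <- as_image_matrix(image)
  n <- nrow(image); m <- ncol(image)
  if (n < 3L || m < 3L)
    stop("prewitt_horizontal() requires an image of at least 3 x 3 pixels")
  pad <- matrix(0, n + 2L, m + 2L)
  pad[2:(n + 1L), 2:(m + 1L)] <- image
  rowdiff <- pad[1:n, , drop = FALSE] - pad[3:(n + 2L), , drop = FALSE]
  rowdiff[, 1:m, drop = FALSE] +
    rowdiff[, 2:(m + 1L), drop = FALSE] +
    rowdiff[, 3:(m + 2L), drop = FALSE]
}

#' Bisigmoidal contrast filter
#'
#' Pushes gradient responses towards saturated extremes while flattening
#' the background towards a uniform mid-level, turning the soft signed
#' output of the Prewitt convolution into firmly segregated contours.
#' For each pixel value `p`, with per-image minimum `m`, maximum `M` and
#' mean `mu`, the filter computes
#' `a1 = min((p - m + mu) / divisor, cap)` and
#' `a2 = min((p - M + mu) / divisor, cap)` (both additionally clamped below
#' at `-cap` so `exp()` can never overflow) and returns
#' `scale * (1 / (1 + exp(a1)) + 1 / (1 + exp(-a2)) - 1/2)`.
#'
#' With the default scale of 24000 the output is confined to the open
#' interval (-12000, 36000): each sigmoid term lies in (0, 1), so the sum
#' minus one half lies in (-1/2, 3/2). A pixel at which both exponent
#' arguments are zero maps to `scale / 2` (both sigmoids equal 1/2).
#'
#' @param image Numeric matrix (typically a signed Prewitt response).
#' @param cfg A [preprocess_config()].
#' @return Numeric matrix of the same dimensions. A constant input (no
#'   contours) returns all zeros.
#' @export
bisigmoid <- function(image, cfg = preprocess_config()) {
  image <- as_image_matrix(image)
  m <- min(image); M <- max(image)
  if (M == m) return(matrix(0, nrow(image), ncol(image)))
  mu <- mean(image)
  a1 <- clamp((image - m + mu) / cfg$sigmoid_divisor,
              -cfg$sigmoid_cap, cfg$sigmoid_cap)
  a2 <- clamp((image - M + mu) / cfg$sigmoid_divisor,
              -cfg$sigmoid_cap, cfg$sigmoid_cap)
  cfg$sigmoid_scale * (1 / (1 + exp(a1)) + 1 / (1 + exp(-a2)) - 0.5)
}

#' Resize an image by bilinear interpolation without anti-aliasing
#'
#' Resizes to `side x side` pixels using bilinear interpolation with no
#' anti-aliasing prefilter, so high-frequency content is subsampled rather
#' than smoothed away.
#'
#' @param image Numeric matrix.
#' @param side Target side length in pixels (>= 8).
#' @return A `side x side` numeric matrix.
#' @export
resize_image <- function(image, side = 55) {
  image <- as_image_matrix(image)
  side <- as.integer(side)
  stopifnot(side >= 8L)
  if (nrow(image) == side && ncol(image) == side) return(image)
  out <- EBImage::resize(image, w = side, h = side,
                         filter = "bilinear", antialias = FALSE)
  matrix(as.numeric(out), side, side)
}

#' Affine intensity normalization
#'
#' Maps pixel values affinely so that the per-image minimum becomes 0 and
#' the per-image maximum becomes `norm_max`:
#' `out = (p - min) / (max - min) * norm_max`. The transform is invariant
#' under positive affine changes of the input (`a * I + b` normalizes
#' identically to `I`) and idempotent.
#'
#' @param image Numeric matrix.
#' @param norm_max Value the maximum maps to (default 65535).
#' @return Numeric matrix in `[0, norm_max]`. A constant image is undefined
#'   under the transform and returns all zeros with a warning.
#' @export
normalize_image <- function(image, norm_max = 65535) {
  image <- as_image_matrix(image)
  m <- min(image); M <- max(image)
  if (M == m) {
    warning("normalize_image(): constant image; returning all zeros")
    return(matrix(0, nrow(image), ncol(image)))
  }
  (image - m) / (M - m) * norm_max
}

#' Apply a circular mask occluding the area outside the droplet
#'
#' Sets to zero every pixel at Euclidean distance `>= side/2 -
#' mask_reduction` from the image centre, removing the droplet rim and the
#' distortions that neighbouring droplets introduce at the image border.
#' Interior pixels are unchanged.
#'
#' @param image Square numeric matrix.
#' @param mask_reduction Pixels subtracted from the half-width to obtain
#'   the mask radius; must be `< side / 2`.
#' @return Numeric matrix with the outside annulus exactly 0.
#' @export
apply_circular_mask <- function(image, mask_reduction = 5) {
  image <- as_image_matrix(image)
  side <- nrow(image)
  if (ncol(image) != side)
    stop("apply_circular_mask() requires a square image")
  if (mask_reduction >= side / 2)
    stop("mask_reduction must be smaller than half the image side")
  radius <- side / 2 - mask_reduction
  ctr <- (side + 1) / 2
  d2 <- outer((seq_len(side) - ctr)^2, (seq_len(side) - ctr)^2, `+`)
  image[d2 >= radius^2] <- 0
  image
}

#' Preprocess one droplet image
#'
#' Runs the full beadline-suppressing pipeline -- horizontal-edge Prewitt
#' convolution, bisigmoidal contrast filter, resize, affine normalization,
#' circular mask, in that order -- or, in `"minimal"` mode, only the resize
#' and normalization steps used as the control condition.
#'
#' @param image Square numeric matrix (a droplet crop, any side length),
#'   or a [droplet_image].
#' @param cfg A [preprocess_config()].
#' @return A `target_side x target_side` numeric matrix with values in
#'   `[0, norm_max]`; in full mode the annulus outside the mask circle is
#'   exactly 0.
#' @export
#' @examples
#' img <- render_droplet(scene_config(n_cells = 1, seed = 7))$image
#' out <- preprocess_droplet(img$pixels, preprocess_config())
#' dim(out)
preprocess_droplet <- function(image, cfg = preprocess_config()) {
  image <- as_image_matrix(image)
  if (nrow(image) != ncol(image))
    stop("preprocess_droplet() requires a square droplet crop")
  if (cfg$mode == "full") {
    out <- prewitt_horizontal(image)
    out <- bisigmoid(out, cfg)
    out <- resize_image(out, cfg$target_side)
    out <- suppressWarnings(normalize_image(out, cfg$norm_max))
    apply_circular_mask(out, cfg$mask_reduction)
  } else {
    out <- resize_image(image, cfg$target_side)
    suppressWarnings(normalize_image(out, cfg$norm_max))
  }
}

#' Preprocess a batch of droplet images
#'
#' @param images A list of square numeric matrices or [droplet_image]
#'   objects.
#' @param cfg A [preprocess_config()].
#' @return A numeric array of shape `(n, target_side, target_side)`.
#' @export
preprocess_batch <- function(images, cfg = preprocess_config()) {
  stopifnot(is.list(images))
  n <- length(images)
  out <- array(0, c(n, cfg$target_side, cfg$target_side))
  for (i in seq_len(n)) out[i, , ] <- preprocess_droplet(images[[i]], cfg)
  out
}

# internal: clamp to [lo, hi]
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# internal: accept droplet_image or plain matrix
as_image_matrix <- function(image) {
  if (inherits(image, "droplet_image")) image <- image$pixels
  if (!is.matrix(image) || !is.numeric(image))
    stop("expected a numeric matrix (or droplet_image)")
  image
}
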