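#' Configuration of the conventional cell-counting baselines
#'
#' Parameters of the three conventional counters benchmarked against the
#' neural classifier, and of droplet localization in chamber mosaics. All
#' values are config-exposed rather than hard-coded; the defaults were
#' tuned on the synthetic fixture set.
#'
#' @param hough_cell_radius_range Length-2 range of candidate cell radii
#'   (pixels) for the circular Hough counter.
#' @param hough_sensitivity Minimum fraction of a circle perimeter that
#'   must be supported by edge pixels for a Hough detection, in `(0, 1]`.
#' @param hough_n_angles Angular resolution of the Hough accumulator.
#' @param mser_delta Level spacing (in threshold steps) over which region
#'   stability is measured.
#' @param mser_area_range Length-2 range of accepted region areas (px^2).
#' @param mser_max_variation Maximum relative area growth for a region to
#'   count as maximally stable.
#' @param mser_n_levels Number of intensity thresholds swept.
#' @param dilatation Length in pixels of the linear structuring elements
#'   of the morphological counter (default 15; structures closer than this
#'   merge into one object).
#' @param circularity_min Minimum circularity (disc = 1) for accepted
#'   regions, in `[0, 1]`.
#' @param edge_floor Absolute gradient-magnitude floor (intensity counts)
#'   below which pixels are never edges, guarding the automatic Otsu
#'   threshold against pure-noise images.
#' @param morph_mask_reduction Pixels subtracted from the image half-width
#'   for the interior mask of the morphological counter.
#' @param morph_min_area Minimum connected-component area kept as an
#'   object (px^2).
#' @param morph_circularity_min Minimum bounding-box circularity of a
#'   kept component; rejects clearly elongated objects such as the bead
#'   column (and anything fused to it), which is not a cell.
#' @param droplet_radius_range,droplet_radius_step Candidate droplet radii
#'   (pixels) for [detect_droplets()].
#' @param droplet_sensitivity Perimeter-support threshold for droplet
#'   detection.
#'
#' @return A list of class `"baseline_config"`.
#' @export
baseline_config <- function(hough_cell_radius_range = c(4, 9),
                            hough_sensitivity = 0.75,
                            hough_n_angles = 64,
                            mser_delta = 2,
                            mser_area_range = c(20, 500),
                            mser_max_variation = 0.5,
                            mser_n_levels = 25,
                            dilatation = 15,
                            circularity_min = 0.5,
                            edge_floor = 12000,
                            morph_mask_reduction = 8,
                            morph_min_area = 20,
                            morph_circularity_min = 0.25,
                            droplet_radius_range = c(35, 70),
                            droplet_radius_step = 2,
                            droplet_sensitivity = 0.4) {
  stopifnot(dilatation >= 1, length(hough_cell_radius_range) == 2,
            hough_cell_radius_range[2] >= hough_cell_radius_range[1],
            hough_sensitivity > 0, hough_sensitivity <= 1,
            length(mser_area_range) == 2,
            circularity_min >= 0, circularity_min <= 1)
  structure(as.list(environment()), class = "baseline_config")
}

#' Map a cell count to a class label
#'
#' `0 -> Empty/0`, `1 -> Single/1`, `>= 2 -> Multiple/2`. Total and
#' monotone: increasing the count never moves the label back towards
#' Empty.
#'
#' @param count Integer vector of non-negative cell counts.
#' @return Integer vector of labels in `{0, 1, 2}`.
#' @export
#' @examples
#' classify_by_count(c(0, 1, 7))
classify_by_count <- function(count) {
  if (any(!is.finite(count)) || any(count < 0))
    stop("classify_by_count(): counts must be non-negative")
  as.integer(pmin(count, 2))
}

# ---- shared edge machinery ------------------------------------------------

# vertical-edge Prewitt (transpose trick on the horizontal kernel)
prewitt_vertical <- function(image) t(prewitt_horizontal(t(image)))

# gradient magnitude from the two Prewitt orientations
gradient_magnitude <- function(image) {
  sqrt(prewitt_horizontal(image)^2 + prewitt_vertical(image)^2)
}

# binary edge map: Otsu on the normalized magnitude, with an absolute floor
edge_map <- function(image, edge_floor) {
  mag <- gradient_magnitude(image)
  mx <- max(mag)
  if (mx <= edge_floor) return(matrix(FALSE, nrow(mag), ncol(mag)))
  thr <- EBImage::otsu(mag / mx, range = c(0, 1))
  mag > pmax(thr * mx, edge_floor)
}

# circular Hough accumulator; returns data.frame(y, x, r, score), score =
# fraction of perimeter supported, already non-max-suppressed
hough_circles <- function(edges, radii, n_angles, sensitivity,
                          suppress = c("pairmin", "overlap")) {
  suppress <- match.arg(suppress)
  H <- nrow(edges); W <- ncol(edges)
  idx <- which(edges)
  if (!length(idx)) return(data.frame(y = numeric(0), x = numeric(0),
                                      r = numeric(0), score = numeric(0)))
  ey <- (idx - 1L) %% H + 1L
  ex <- (idx - 1L) %/% H + 1L
  angles <- seq(0, 2 * pi, length.out = n_angles + 1L)[-(n_angles + 1L)]
  cand <- vector("list", length(radii))
  vote_maps <- vector("list", length(radii))
  for (k in seq_along(radii)) {
    r <- radii[k]
    votes <- integer(H * W)
    for (a in angles) {
      cy <- as.integer(round(ey - r * sin(a)))
      cx <- as.integer(round(ex - r * cos(a)))
      ok <- cy >= 1L & cy <= H & cx >= 1L & cx <= W
      if (any(ok)) {
        lin <- (cx[ok] - 1L) * H + cy[ok]
        tab <- tabulate(lin, nbins = H * W)
        votes <- votes + tab
      }
    }
    vote_maps[[k]] <- matrix(votes, H, W)
    score <- votes / n_angles
    hit <- which(score >= sensitivity)
    if (length(hit))
      cand[[k]] <- data.frame(y = (hit - 1L) %% H + 1L,
                              x = (hit - 1L) %/% H + 1L,
                              r = r, ri = k, score = score[hit])
  }
  cand <- do.call(rbind, cand)
  if (is.null(cand) || !nrow(cand))
    return(data.frame(y = numeric(0), x = numeric(0),
                      r = numeric(0), score = numeric(0)))
  # greedy suppression, keeping the higher score: "pairmin" drops centres
  # closer than the smaller radius of the pair (droplet localization);
  # "overlap" drops substantially overlapping circles (centres closer than
  # the mean of the two radii), needed for annular cells whose inner and
  # outer contours both vote
  cand <- cand[order(-cand$score), , drop = FALSE]
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (i == 1L) { keep[1L] <- TRUE; next }
    kept <- cand[keep, , drop = FALSE]
    d <- sqrt((kept$y - cand$y[i])^2 + (kept$x - cand$x[i])^2)
    lim <- if (suppress == "pairmin") pmin(kept$r, cand$r[i])
           else (kept$r + cand$r[i]) / 2
    keep[i] <- all(d >= lim)
  }
  out <- cand[keep, , drop = FALSE]
  # sub-pixel centre refinement: vote-weighted centroid over a small
  # window of the accumulator slice the detection came from
  for (i in seq_len(nrow(out))) {
    vm <- vote_maps[[out$ri[i]]]
    ys <- max(1, out$y[i] - 2):min(H, out$y[i] + 2)
    xs <- max(1, out$x[i] - 2):min(W, out$x[i] + 2)
    w <- vm[ys, xs, drop = FALSE]
    if (sum(w) > 0) {
      out$y[i] <- sum(rowSums(w) * ys) / sum(w)
      out$x[i] <- sum(colSums(w) * xs) / sum(w)
    }
  }
  out$ri <- NULL
  rownames(out) <- NULL
  out
}

#' Locate droplets in a chamber mosaic by circular Hough transform
#'
#' Detects circles over the configured droplet-radius range; detections
#' are sorted by accumulator score and overlapping ones (centre distance
#' smaller than the smaller radius of the pair) are suppressed, keeping
#' the higher score. An empty result is valid on a blank image.
#'
#' @param chamber 2D numeric intensity matrix.
#' @param cfg A [baseline_config()].
#' @return Data.frame `center_y, center_x, radius, score`, sorted by
#'   decreasing score.
#' @export
detect_droplets <- function(chamber, cfg = baseline_config()) {
  stopifnot(is.matrix(chamber))
  edges <- edge_map(chamber, cfg$edge_floor)
  radii <- seq(cfg$droplet_radius_range[1], cfg$droplet_radius_range[2],
               by = cfg$droplet_radius_step)
  det <- hough_circles(edges, radii, cfg$hough_n_angles,
                       cfg$droplet_sensitivity)
  data.frame(center_y = det$y, center_x = det$x, radius = det$r,
             score = det$score)
}

#' Crop one droplet from a chamber mosaic
#'
#' Square crop of side `2 * radius` (rounded up to even), centred on the
#' droplet; parts falling outside the mosaic are padded with the chamber's
#' median background so border droplets keep the same crop geometry.
#'
#' @param chamber 2D numeric matrix.
#' @param center `(row, col)` centre, 1-based.
#' @param radius Droplet radius in pixels.
#' @return A [droplet_image] of side `2 * ceiling(radius)` (even).
#' @export
crop_droplet <- function(chamber, center, radius) {
  stopifnot(is.matrix(chamber), length(center) == 2, radius > 0)
  side <- 2L * as.integer(ceiling(radius))
  half <- side / 2
  pad <- stats::median(chamber)
  out <- matrix(pad, side, side)
  r0 <- round(center[1]) - half; c0 <- round(center[2]) - half
  rows <- (r0 + 1):(r0 + side); cols <- (c0 + 1):(c0 + side)
  rok <- rows >= 1 & rows <= nrow(chamber)
  cok <- cols >= 1 & cols <= ncol(chamber)
  out[which(rok), which(cok)] <- chamber[rows[rok], cols[cok]]
  droplet_image(out, droplet_radius = radius)
}

# interior mask helper: TRUE inside radius (side/2 - reduction) of centre
interior_mask <- function(side, reduction) {
  ctr <- (side + 1) / 2
  radius <- side / 2 - reduction
  d2 <- outer((seq_len(side) - ctr)^2, (seq_len(side) - ctr)^2, `+`)
  d2 < radius^2
}

#' Count cells by circular Hough transform
#'
#' Edge pixels inside the droplet vote for circle centres over the
#' configured cell-radius range; accepted circles must reach the
#' perimeter-support threshold and lie strictly inside the droplet (centre
#' distance from the image centre below `droplet_radius - r`).
#'
#' @param droplet A [droplet_image] or square numeric matrix.
#' @param cfg A [baseline_config()].
#' @return Integer cell count.
#' @export
count_cells_hough <- function(droplet, cfg = baseline_config()) {
  img <- as_image_matrix(droplet)
  R <- droplet_radius_of(droplet, img)
  side <- nrow(img)
  edges <- edge_map(img, cfg$edge_floor)
  edges <- edges & interior_mask(side, side / 2 - (R - 2))
  radii <- seq(cfg$hough_cell_radius_range[1], cfg$hough_cell_radius_range[2])
  det <- hough_circles(edges, radii, cfg$hough_n_angles,
                       cfg$hough_sensitivity, suppress = "overlap")
  if (!nrow(det)) return(0L)
  ctr <- (side + 1) / 2
  d <- sqrt((det$y - ctr)^2 + (det$x - ctr)^2)
  sum(d < R - det$r)
}

#' Count cells by maximally stable extremal regions
#'
#' Sweeps intensity thresholds, tracks dark connected regions (keyed by
#' their minimum-intensity pixel) across levels, and keeps regions whose
#' area is maximally stable, i.e. changes least over `mser_delta` levels
#' and below `mser_max_variation`. Stable regions are then filtered by
#' area range, circularity and position inside the droplet; proposals
#' outside the rim (e.g. neighbouring-droplet fragments) are discarded.
#'
#' @inheritParams count_cells_hough
#' @return Integer cell count.
#' @export
count_cells_mser <- function(droplet, cfg = baseline_config()) {
  img <- as_image_matrix(droplet)
  R <- droplet_radius_of(droplet, img)
  side <- nrow(img)
  inside <- interior_mask(side, side / 2 - (R - 2))
  x <- img / 65535
  levels <- seq(0.02, 0.98, length.out = cfg$mser_n_levels)
  # per level: list keyed by seed pixel -> c(area, cy, cx, bbox h, bbox w)
  per_level <- vector("list", length(levels))
  for (li in seq_along(levels)) {
    bw <- (x < levels[li]) & inside
    if (!any(bw)) { per_level[[li]] <- list(); next }
    lab <- EBImage::bwlabel(bw)
    lab <- matrix(as.integer(lab), side, side)
    nlab <- max(lab)
    comp <- list()
    for (ci in seq_len(nlab)) {
      pix <- which(lab == ci)
      seed <- pix[which.min(x[pix])]
      py <- (pix - 1L) %% side + 1L
      px <- (pix - 1L) %/% side + 1L
      comp[[as.character(seed)]] <-
        c(area = length(pix), cy = mean(py), cx = mean(px),
          h = diff(range(py)) + 1, w = diff(range(px)) + 1)
    }
    per_level[[li]] <- comp
  }
  # stability of each chain (same seed key) across levels
  delta <- cfg$mser_delta
  stable <- list()
  for (li in seq_along(levels)) {
    if (li - delta < 1 || li + delta > length(levels)) next
    for (key in names(per_level[[li]])) {
      lo <- per_level[[li - delta]][[key]]
      hi <- per_level[[li + delta]][[key]]
      cur <- per_level[[li]][[key]]
      if (is.null(lo) || is.null(hi)) next
      v <- (hi["area"] - lo["area"]) / cur["area"]
      prev <- stable[[key]]
      if (is.null(prev) || v < prev["v"])
        stable[[key]] <- c(cur, v = unname(v))
    }
  }
  if (!length(stable)) return(0L)
  ctr <- (side + 1) / 2
  n <- 0L
  kept <- matrix(numeric(0), 0, 2)
  for (key in names(stable)) {
    s <- stable[[key]]
    if (s["v"] > cfg$mser_max_variation) next
    if (s["area"] < cfg$mser_area_range[1] ||
        s["area"] > cfg$mser_area_range[2]) next
    circ <- 4 * s["area"] / (pi * max(s["h"], s["w"])^2)
    if (circ < cfg$circularity_min) next
    if (sqrt((s["cy"] - ctr)^2 + (s["cx"] - ctr)^2) >= R - 2) next
    if (nrow(kept) &&
        any(sqrt((kept[, 1] - s["cy"])^2 + (kept[, 2] - s["cx"])^2) <
            cfg$hough_cell_radius_range[1])) next
    kept <- rbind(kept, c(s["cy"], s["cx"]))
    n <- n + 1L
  }
  n
}

#' Count cells by the morphological segmentation sequence
#'
#' Implements, in order: edge detection (gradient magnitude thresholded at
#' Otsu's level with an absolute floor), a circular interior mask, dilation
#' with linear structuring elements of length `dilatation` in two
#' orientations, hole filling, erosion with the same elements, connected
#' components, and a count of component centroids. Structures closer than
#' `dilatation` pixels merge into a single object.
#'
#' @inheritParams count_cells_hough
#' @return Integer cell count.
#' @export
count_cells_morphological <- function(droplet, cfg = baseline_config()) {
  img <- as_image_matrix(droplet)
  side <- nrow(img)
  edges <- edge_map(img, cfg$edge_floor)
  edges <- edges & interior_mask(side, cfg$morph_mask_reduction)
  if (!any(edges)) return(0L)
  len <- as.integer(cfg$dilatation)
  if (len %% 2L == 0L) len <- len + 1L
  se_v <- EBImage::makeBrush(len, shape = "line", angle = 0)
  se_h <- EBImage::makeBrush(len, shape = "line", angle = 90)
  bw <- EBImage::dilate(EBImage::dilate(edges * 1, se_v), se_h)
  bw <- EBImage::fillHull(bw)
  bw <- EBImage::erode(EBImage::erode(bw, se_v), se_h)
  lab <- EBImage::bwlabel(bw)
  lab <- matrix(as.integer(lab), side, side)
  if (max(lab) == 0L) return(0L)
  n <- 0L
  for (ci in seq_len(max(lab))) {
    pix <- which(lab == ci)
    if (length(pix) < cfg$morph_min_area) next
    py <- (pix - 1L) %% side + 1L
    px <- (pix - 1L) %/% side + 1L
    ext <- max(diff(range(py)), diff(range(px))) + 1
    if (4 * length(pix) / (pi * ext^2) < cfg$morph_circularity_min) next
    n <- n + 1L
  }
  n
}

#' Run a conventional counter over a set of droplets
#'
#' @param images List of [droplet_image] objects (or matrices).
#' @param labels Integer vector of true labels (same length), or `NULL`.
#' @param method One of `"hough"`, `"mser"`, `"morph"`.
#' @param cfg A [baseline_config()].
#' @return Data.frame `true_label` (if given), `count`, `pred_label`.
#' @export
run_baseline <- function(images, labels = NULL,
                         method = c("hough", "mser", "morph"),
                         cfg = baseline_config()) {
  method <- match.arg(method)
  fn <- switch(method, hough = count_cells_hough, mser = count_cells_mser,
               morph = count_cells_morphological)
  counts <- vapply(images, fn, integer(1), cfg = cfg)
  out <- data.frame(count = counts, pred_label = classify_by_count(counts))
  if (!is.null(labels)) out <- cbind(true_label = as.integer(labels), out)
  out
}

# droplet radius metadata, or the cropped-at-diameter convention
droplet_radius_of <- function(droplet, img) {
  if (inherits(droplet, "droplet_image")) droplet$droplet_radius
  else nrow(img) / 2 - 2
}
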