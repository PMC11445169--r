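#' Synthetic droplet scene configuration
#'
#' Describes one synthetic brightfield droplet crop: a dark circular rim on
#' a uniform oil background, an optional dark vertical column of
#' paramagnetic nanobeads (the "beadline") spanning the droplet interior
#' with occasional blob-like morphological irregularities, zero or more
#' defocused cells rendered as dark rings with slightly brighter centres,
#' arc fragments of neighbouring droplets intruding at the image border,
#' and Gaussian sensor noise. All intensities are on the native 16-bit
#' scale `[0, 65535]`.
#'
#' The ground-truth class label is a pure function of `n_cells`
#' (0 = Empty, 1 = Single, >= 2 = Multiple). Cells may intersect the
#' beadline -- partial occlusion of cells by the bead column, and bead
#' blobs that mimic cells, are exactly the failure modes of conventional
#' counters that the preprocessing pipeline addresses -- and darkness
#' composes by pixelwise minimum, so the darkest structure wins.
#'
#' @param image_side Side of the square crop in pixels.
#' @param droplet_radius Droplet radius in pixels (default
#'   `image_side / 2 - 2`, i.e. the crop is the droplet diameter).
#' @param n_cells Number of cells to place (integer >= 0).
#' @param cell_radius_range Length-2 range of cell radii in pixels.
#' @param beadline Logical; render the vertical bead column?
#' @param beadline_width Width of the bead column in pixels.
#' @param beadline_irregularity Per-site probability of a blob artifact
#'   along the line (sites every ~8 px); blobs are 1.5-2x the line width.
#' @param neighbor_fragments Number of neighbouring-droplet rim arcs
#'   intruding at the border.
#' @param background_level,rim_darkness,cell_darkness,bead_darkness
#'   Intensity levels in `[0, 65535]` of the oil background, droplet rim,
#'   cell ring and bead column respectively (lower = darker).
#' @param noise_sd Standard deviation of the additive Gaussian sensor
#'   noise, in intensity counts.
#' @param seed Integer seed; identical config + seed gives bit-identical
#'   images.
#'
#' @return A list of class `"scene_config"`.
#' @export
#' @examples
#' cfg <- scene_config(n_cells = 1, beadline = TRUE, seed = 42)
#' drop <- render_droplet(cfg)
#' drop$label
scene_config <- function(image_side = 110,
                         droplet_radius = image_side / 2 - 2,
                         n_cells = 0,
                         cell_radius_range = c(6, 9),
                         beadline = FALSE,
                         beadline_width = 4,
                         beadline_irregularity = 0.05,
                         neighbor_fragments = 2,
                         background_level = 32000,
                         rim_darkness = 3000,
                         cell_darkness = 150,
                         bead_darkness = 600,
                         noise_sd = 150,
                         seed = NULL) {
  stopifnot(image_side >= 16, droplet_radius > 0,
            droplet_radius <= image_side / 2,
            n_cells >= 0, length(cell_radius_range) == 2,
            cell_radius_range[1] > 0,
            cell_radius_range[2] >= cell_radius_range[1],
            beadline_width >= 1,
            beadline_irregularity >= 0, beadline_irregularity <= 1,
            neighbor_fragments >= 0, noise_sd >= 0)
  lv <- c(background_level, rim_darkness, cell_darkness, bead_darkness)
  stopifnot(all(lv >= 0), all(lv <= 65535))
  structure(list(image_side = as.integer(image_side),
                 droplet_radius = droplet_radius,
                 n_cells = as.integer(n_cells),
                 cell_radius_range = cell_radius_range,
                 beadline = isTRUE(beadline),
                 beadline_width = beadline_width,
                 beadline_irregularity = beadline_irregularity,
                 neighbor_fragments = as.integer(neighbor_fragments),
                 background_level = background_level,
                 rim_darkness = rim_darkness,
                 cell_darkness = cell_darkness,
                 bead_darkness = bead_darkness,
                 noise_sd = noise_sd,
                 seed = seed),
            class = "scene_config")
}

#' Render one synthetic droplet image
#'
#' Draws the scene described by `config` deterministically from its seed:
#' rim, optional beadline with blob irregularities, `n_cells` cells placed
#' uniformly inside the droplet with non-overlapping centres (bounded
#' retries; placement failure is an explicit error, never silent
#' under-placement), neighbour-droplet arcs, then Gaussian noise, clipping
#' to `[0, 65535]` and rounding to integer counts.
#'
#' @param config A [scene_config()] with `seed` set.
#' @return A list of class `"labeled_droplet"` with elements `image` (a
#'   [droplet_image]), `label` (integer 0/1/2), `n_cells`, and
#'   `provenance` (the config).
#' @export
render_droplet <- function(config) {
  stopifnot(inherits(config, "scene_config"))
  if (is.null(config$seed))
    stop("render_droplet() requires a seed in the scene config")
  withr::with_seed(as.integer(config$seed), {
    px <- render_droplet_impl(config)
  })
  img <- droplet_image(px, droplet_radius = config$droplet_radius)
  structure(list(image = img,
                 label = classify_by_count(config$n_cells),
                 n_cells = config$n_cells,
                 provenance = config),
            class = "labeled_droplet")
}

# scene painter; assumes RNG state already set
render_droplet_impl <- function(cfg) {
  s <- cfg$image_side
  R <- cfg$droplet_radius
  ctr <- (s + 1) / 2
  xs <- seq_len(s)
  dy <- matrix(xs - ctr, s, s)          # row offsets
  dx <- matrix(xs - ctr, s, s, byrow = TRUE)
  d <- sqrt(dy^2 + dx^2)

  img <- matrix(cfg$background_level, s, s)

  # droplet rim: dark annulus of ~3 px thickness at the droplet radius
  rim <- abs(d - R) <= 1.5
  img[rim] <- pmin(img[rim], cfg$rim_darkness)

  # neighbouring droplet arcs intruding at the border
  if (cfg$neighbor_fragments > 0) {
    for (i in seq_len(cfg$neighbor_fragments)) {
      th <- runif(1, 0, 2 * pi)
      gap <- runif(1, 2, 6)
      ncy <- ctr + (2 * R + gap) * sin(th)
      ncx <- ctr + (2 * R + gap) * cos(th)
      nd <- sqrt((dy + ctr - ncy)^2 + (dx + ctr - ncx)^2)
      arc <- abs(nd - R) <= 1.5 & d > R + 1.5
      img[arc] <- pmin(img[arc], cfg$rim_darkness)
    }
  }

  # beadline: vertical bead column through the centre, spanning the droplet
  if (cfg$beadline) {
    half_w <- cfg$beadline_width / 2
    line <- abs(dx) <= half_w & d <= R
    img[line] <- pmin(img[line], cfg$bead_darkness)
    # occasional blob irregularities along the line
    chord <- sqrt(max(R^2 - half_w^2, 0))
    sites <- seq(ctr - chord + 4, ctr + chord - 4, by = 8)
    for (sy in sites) {
      if (runif(1) < cfg$beadline_irregularity) {
        br <- runif(1, 0.75, 1) * cfg$beadline_width
        bd <- sqrt((dy + ctr - sy)^2 + dx^2)
        blob <- bd <= br & d <= R - 1.5
        img[blob] <- pmin(img[blob], cfg$bead_darkness * 0.95)
      }
    }
  }

  # cells: dark rings with slightly brighter centres (defocused look)
  if (cfg$n_cells > 0) {
    placed <- matrix(numeric(0), 0, 3)  # y, x, r
    max_try <- 200L
    for (i in seq_len(cfg$n_cells)) {
      r <- runif(1, cfg$cell_radius_range[1], cfg$cell_radius_range[2])
      ok <- FALSE
      for (t in seq_len(max_try)) {
        rho <- sqrt(runif(1)) * max(R - r - 3, 1)
        th <- runif(1, 0, 2 * pi)
        cy <- ctr + rho * sin(th)
        cx <- ctr + rho * cos(th)
        if (nrow(placed) == 0 ||
            all(sqrt((placed[, 1] - cy)^2 + (placed[, 2] - cx)^2) >=
                placed[, 3] + r)) {
          ok <- TRUE
          break
        }
      }
      if (!ok)
        stop("render_droplet(): could not place ", cfg$n_cells,
             " non-overlapping cells inside the droplet after ", max_try,
             " attempts; the droplet is too small for this cell count")
      placed <- rbind(placed, c(cy, cx, r))
      cd <- sqrt((dy + ctr - cy)^2 + (dx + ctr - cx)^2)
      ring <- cd <= r & cd >= r * 0.55
      core <- cd < r * 0.55
      centre_level <- cfg$background_level -
        0.35 * (cfg$background_level - cfg$cell_darkness)
      img[ring] <- pmin(img[ring], cfg$cell_darkness)
      img[core] <- pmin(img[core], centre_level)
    }
  }

  if (cfg$noise_sd > 0)
    img <- img + matrix(rnorm(s * s, 0, cfg$noise_sd), s, s)
  matrix(as.numeric(round(pmin(pmax(img, 0), 65535))), s, s)
}

#' Generate a balanced labeled synthetic dataset on disk
#'
#' Writes `3 * n_per_class` single-droplet 16-bit TIFFs (Empty, Single and
#' Multiple classes, exactly balanced) plus a CSV manifest with columns
#' `file,label,n_cells,seed`. Multiple-cell droplets draw their cell count
#' uniformly from 2-4. Per-image seeds are derived deterministically from
#' the master seed, so two runs with the same seed produce identical files.
#'
#' @param n_per_class Images per class (>= 1).
#' @param config_template A [scene_config()]; its `n_cells` and `seed` are
#'   overridden per image.
#' @param out_dir Output directory (created if absent).
#' @param seed Master integer seed.
#' @return The manifest as a data.frame (invisibly also written to
#'   `manifest.csv` in `out_dir`).
#' @export
generate_dataset <- function(n_per_class, config_template = scene_config(),
                             out_dir, seed) {
  stopifnot(n_per_class >= 1)
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("generate_dataset(): cannot create output directory ", out_dir)
  n_total <- 3L * as.integer(n_per_class)
  withr::with_seed(as.integer(seed), {
    seeds <- sample.int(.Machine$integer.max - 1L, n_total)
    multi_counts <- sample(2:4, n_per_class, replace = TRUE)
  })
  labels <- rep(0:2, each = n_per_class)
  n_cells <- c(rep(0L, n_per_class), rep(1L, n_per_class), multi_counts)
  files <- sprintf("droplet_%05d_c%d.tif", seq_len(n_total), labels)
  for (i in seq_len(n_total)) {
    cfg <- config_template
    cfg$n_cells <- as.integer(n_cells[i])
    cfg$seed <- seeds[i]
    drop <- render_droplet(cfg)
    write_droplet_tiff(drop$image, file.path(out_dir, files[i]))
  }
  manifest <- data.frame(file = files, label = labels,
                         n_cells = as.integer(n_cells), seed = seeds,
                         stringsAsFactors = FALSE)
  write_manifest(manifest, file.path(out_dir, "manifest.csv"))
  manifest
}

#' Render a synthetic chamber mosaic with known droplet positions
#'
#' Packs `grid_rows x grid_cols` droplets on a hexagonal-ish lattice whose
#' pitch exceeds the droplet diameter, composes the individual scenes onto
#' a common background by pixelwise minimum, and finally adds chamber-wide
#' sensor noise. Returns the image together with the planted ground truth,
#' for droplet-detection tests.
#'
#' @param grid_rows,grid_cols Lattice dimensions (>= 1).
#' @param config_template A [scene_config()]; per-droplet cell counts are
#'   drawn uniformly from 0-2.
#' @param seed Integer seed.
#' @return A list with `image` (numeric matrix) and `droplets` (data.frame
#'   `row, col, center_y, center_x, radius, n_cells, label`).
#' @export
render_chamber <- function(grid_rows, grid_cols,
                           config_template = scene_config(), seed) {
  stopifnot(grid_rows >= 1, grid_cols >= 1)
  cfg <- config_template
  R <- cfg$droplet_radius
  s <- cfg$image_side
  pitch <- 2 * R + 8
  margin <- s / 2 + 2
  height <- ceiling(2 * margin + (grid_rows - 1) * pitch)
  width <- ceiling(2 * margin + (grid_cols - 1) * pitch + pitch / 2)
  withr::with_seed(as.integer(seed), {
    seeds <- sample.int(.Machine$integer.max - 1L, grid_rows * grid_cols)
    counts <- sample(0:2, grid_rows * grid_cols, replace = TRUE)
    chamber <- matrix(cfg$background_level, height, width)
    planted <- NULL
    k <- 0L
    for (i in seq_len(grid_rows)) {
      for (j in seq_len(grid_cols)) {
        k <- k + 1L
        cy <- margin + (i - 1) * pitch
        cx <- margin + (j - 1) * pitch + (i %% 2) * pitch / 2
        dcfg <- cfg
        dcfg$n_cells <- counts[k]
        dcfg$neighbor_fragments <- 0L   # neighbours are real here
        dcfg$noise_sd <- 0              # chamber-wide noise added below
        dcfg$seed <- seeds[k]
        tile <- render_droplet(dcfg)$image$pixels
        r0 <- round(cy - (s - 1) / 2); c0 <- round(cx - (s - 1) / 2)
        rows <- r0:(r0 + s - 1); cols <- c0:(c0 + s - 1)
        chamber[rows, cols] <- pmin(chamber[rows, cols], tile)
        # record where the tile centre actually landed after rounding
        planted <- rbind(planted,
                         data.frame(row = i, col = j,
                                    center_y = r0 + (s - 1) / 2,
                                    center_x = c0 + (s - 1) / 2, radius = R,
                                    n_cells = counts[k],
                                    label = classify_by_count(counts[k])))
      }
    }
    if (cfg$noise_sd > 0)
      chamber <- chamber +
        matrix(rnorm(length(chamber), 0, cfg$noise_sd), height, width)
  })
  chamber <- matrix(as.numeric(round(pmin(pmax(chamber, 0), 65535))),
                    height, width)
  list(image = chamber, droplets = planted)
}
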