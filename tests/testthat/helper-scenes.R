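# shared fixture helpers: small deterministic scenes

quiet_scene <- function(n_cells = 0, beadline = FALSE, seed = 1, ...) {
  scene_config(n_cells = n_cells, beadline = beadline, noise_sd = 0,
               neighbor_fragments = 0, beadline_irregularity = 0,
               seed = seed, ...)
}

# draw a blank droplet image (background + rim only) and paint filled dark
# discs at chosen centres; used where tests need exact cell geometry
disc_droplet <- function(side = 110, centers = NULL, radius = 5,
                         bg = 32000, dark = 150, rim = 3000) {
  ctr <- (side + 1) / 2
  R <- side / 2 - 2
  dy <- matrix(seq_len(side) - ctr, side, side)
  dx <- matrix(seq_len(side) - ctr, side, side, byrow = TRUE)
  d <- sqrt(dy^2 + dx^2)
  img <- matrix(bg, side, side)
  img[abs(d - R) <= 1.5] <- rim
  if (!is.null(centers)) {
    for (i in seq_len(nrow(centers))) {
      cd <- sqrt((dy + ctr - centers[i, 1])^2 + (dx + ctr - centers[i, 2])^2)
      img[cd <= radius] <- dark
    }
  }
  droplet_image(img)
}
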