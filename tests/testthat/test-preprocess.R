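test_that("horizontal Prewitt response vanishes on vertically constant structure", {
  # constant image: derivative of a constant is zero everywhere away from
  # the zero-padded border, where the pad itself is the only structure
  pw0 <- prewitt_horizontal(matrix(42, 7, 7))
  expect_equal(pw0[2:6, ], matrix(0, 5, 7))
  expect_equal(pw0[1, 3], -3 * 42)  # pad-vs-constant step at the border
  expect_equal(pw0[7, 3], 3 * 42)
  # column-constant stripe (ideal beadline): zero response in the interior
  img <- matrix(100, 9, 9)
  img[, 4:6] <- 13
  pw <- prewitt_horizontal(img)
  expect_true(all(pw[2:8, ] == 0))
  expect_error(prewitt_horizontal(matrix(1, 2, 5)), "at least 3 x 3")
})

test_that("horizontal edges map to magnitude-3h responses with the operator's asymmetry", {
  h <- 7
  step <- rbind(matrix(0, 3, 5), matrix(h, 3, 5))
  pw <- prewitt_horizontal(step)
  # rows straddling the step see the full kernel weight: magnitude 3h
  expect_equal(pw[3, 2:4], rep(-3 * h, 3))
  expect_equal(pw[4, 2:4], rep(-3 * h, 3))
  # rows away from the step (and from the zero-padded border) are flat
  expect_equal(pw[2, 2:4], rep(0, 3))
  expect_equal(pw[5, 2:4], rep(0, 3))
  # a dark horizontal band: its two edges respond with opposite signs
  # (the white-above/black-below asymmetry of the operator)
  band <- matrix(10, 9, 5); band[5, ] <- 0
  pb <- prewitt_horizontal(band)
  expect_equal(pb[4, 2:4], rep(30, 3))
  expect_equal(pb[6, 2:4], rep(-30, 3))
})

test_that("bisigmoid matches a direct evaluation of its formula", {
  cfg <- preprocess_config()
  img <- matrix(c(-5000, -300, 0, 120, 2500, 40000, -100, 7, 3), 3, 3)
  m <- min(img); M <- max(img); mu <- mean(img)
  a1 <- pmin(pmax((img - m + mu) / 600, -700), 700)
  a2 <- pmin(pmax((img - M + mu) / 600, -700), 700)
  expected <- 24000 * (1 / (1 + exp(a1)) + 1 / (1 + exp(-a2)) - 0.5)
  expect_equal(bisigmoid(img, cfg), expected)
})

test_that("bisigmoid output is bounded and never overflows", {
  cfg <- preprocess_config()
  set.seed(4)
  for (i in 1:5) {
    img <- matrix(rnorm(400, 0, 10^runif(1, 1, 5)), 20, 20)
    out <- bisigmoid(img, cfg)
    expect_true(all(is.finite(out)))
    # limits of the two sigmoid terms: [-scale/2, 3*scale/2] (the open
    # mathematical bounds are attained at double precision saturation)
    expect_true(all(out >= -12000 & out <= 36000))
  }
  # huge values: exponent argument capped at 700, exp() stays finite
  out <- bisigmoid(matrix(c(-1e9, 0, 1e9, 2), 2, 2), cfg)
  expect_true(all(is.finite(out)))
  # a constant image has no contours: defined all-zero fallback
  expect_equal(bisigmoid(matrix(5, 4, 4), cfg), matrix(0, 4, 4))
})

test_that("resize is bilinear without anti-aliasing and preserves constants", {
  img <- matrix(rnorm(55 * 55), 55, 55)
  expect_identical(resize_image(img, 55), img)
  expect_equal(dim(resize_image(matrix(rnorm(110 * 110), 110), 55)), c(55L, 55L))
  expect_equal(resize_image(matrix(3.5, 110, 110), 55), matrix(3.5, 55, 55))
})

test_that("normalization maps extremes exactly and is affine invariant", {
  set.seed(7)
  img <- matrix(runif(900, 5000, 30000), 30, 30)
  out <- normalize_image(img)
  expect_equal(out[which.max(img)], 65535)
  expect_equal(out[which.min(img)], 0)
  expect_true(all(out >= 0 & out <= 65535))
  # invariance under positive affine maps, and idempotence
  expect_equal(normalize_image(3.7 * img - 1234), out, tolerance = 1e-12)
  expect_lt(max(abs(normalize_image(out) - out)), 1)
  expect_warning(z <- normalize_image(matrix(9, 4, 4)), "constant")
  expect_equal(z, matrix(0, 4, 4))
})

test_that("circular mask zeroes the annulus and matches a lattice oracle", {
  set.seed(1)
  img <- matrix(runif(55 * 55, 1, 2), 55, 55)  # strictly positive
  out <- apply_circular_mask(img, 5)
  expect_equal(out[1, 1], 0)  # all four corners
  expect_equal(out[1, 55], 0)
  expect_equal(out[55, 1], 0)
  expect_equal(out[55, 55], 0)
  expect_equal(out[28, 28], img[28, 28])  # centre untouched
  # brute-force lattice enumeration of surviving pixels
  ctr <- 28; radius <- 55 / 2 - 5
  survive <- 0L
  for (i in 1:55) for (j in 1:55)
    if ((i - ctr)^2 + (j - ctr)^2 < radius^2) survive <- survive + 1L
  expect_equal(sum(out != 0), survive)
  expect_error(apply_circular_mask(img, 30), "smaller than half")
})

test_that("full pipeline yields masked 55x55 output in range, batched as (n, 55, 55)", {
  cfg <- preprocess_config()
  drops <- lapply(1:3, function(i)
    render_droplet(scene_config(n_cells = i - 1, beadline = TRUE,
                                seed = 40 + i))$image)
  out <- preprocess_droplet(drops[[2]], cfg)
  expect_equal(dim(out), c(55L, 55L))
  expect_true(all(out >= 0 & out <= 65535))
  ctr <- 28; radius <- 55 / 2 - cfg$mask_reduction
  ann <- outer((1:55 - ctr)^2, (1:55 - ctr)^2, `+`) >= radius^2
  expect_true(all(out[ann] == 0))
  batch <- preprocess_batch(drops, cfg)
  expect_equal(dim(batch), c(3L, 55L, 55L))
  # determinism: no RNG anywhere in this module
  expect_identical(preprocess_droplet(drops[[2]], cfg), out)
})

test_that("an ideal beadline is suppressed by full preprocessing", {
  cfg <- preprocess_config()
  for (nc in 0:1) {
    plain <- render_droplet(quiet_scene(n_cells = nc, seed = 60 + nc))
    lined <- render_droplet(quiet_scene(n_cells = nc, beadline = TRUE,
                                        seed = 60 + nc))
    o1 <- preprocess_droplet(plain$image, cfg)
    o2 <- preprocess_droplet(lined$image, cfg)
    # same scene +/- the vertical stripe: outputs differ by < 1% of range
    expect_lt(mean(abs(o1 - o2)) / 65535, 0.01)
  }
  # minimal mode is the control: the beadline stays plainly visible
  mcfg <- preprocess_config(mode = "minimal")
  m1 <- preprocess_droplet(render_droplet(quiet_scene(seed = 61))$image, mcfg)
  m2 <- preprocess_droplet(render_droplet(quiet_scene(beadline = TRUE,
                                                      seed = 61))$image, mcfg)
  expect_gt(mean(abs(m1 - m2)) / 65535, 0.02)
})
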