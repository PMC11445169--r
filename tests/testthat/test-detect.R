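test_that("classify_by_count is total, monotone and matches the class definition", {
  expect_equal(classify_by_count(0), 0L)   # Empty/0
  expect_equal(classify_by_count(1), 1L)   # Single/1
  expect_equal(classify_by_count(7), 2L)   # "two or more" -> Multiple/2
  counts <- 0:10
  labs <- classify_by_count(counts)
  expect_true(all(diff(labs) >= 0))        # monotone in the count
  expect_error(classify_by_count(-1), "non-negative")
})

test_that("droplet detection recovers planted chambers and handles degenerate input", {
  scene <- quiet_scene(seed = 1)
  ch <- render_chamber(3, 3, scene, seed = 41)
  det <- detect_droplets(ch$image)
  expect_gte(nrow(det), 9)
  hits <- 0
  for (i in seq_len(nrow(ch$droplets))) {
    d <- sqrt((det$center_y - ch$droplets$center_y[i])^2 +
                (det$center_x - ch$droplets$center_x[i])^2)
    j <- which.min(d)
    if (d[j] <= 2 && abs(det$radius[j] - ch$droplets$radius[i]) <=
        0.1 * ch$droplets$radius[i]) hits <- hits + 1
  }
  expect_gte(hits / nrow(ch$droplets), 0.95)
  # blank image: empty result is valid
  expect_equal(nrow(detect_droplets(matrix(1000, 120, 120))), 0L)
})

test_that("overlapping droplet detections are suppressed, keeping one", {
  # two rims closer than one radius: the suppression rule keeps exactly one
  side <- 160
  ctr1 <- c(80, 70); ctr2 <- c(80, 95); R <- 45
  img <- matrix(32000, side, side)
  for (ctr in list(ctr1, ctr2)) {
    dy <- matrix(seq_len(side) - ctr[1], side, side)
    dx <- matrix(seq_len(side) - ctr[2], side, side, byrow = TRUE)
    img[abs(sqrt(dy^2 + dx^2) - R) <= 1.5] <- 3000
  }
  det <- detect_droplets(img, baseline_config(droplet_radius_range = c(40, 50)))
  expect_equal(nrow(det), 1L)
})

test_that("crop_droplet produces centred even-sided crops with border padding", {
  ch <- render_chamber(2, 2, quiet_scene(seed = 2), seed = 43)
  p <- ch$droplets[1, ]
  crop <- crop_droplet(ch$image, c(p$center_y, p$center_x), 50)
  expect_equal(dim(crop$pixels), c(100L, 100L))
  # crop centre neighbourhood equals the chamber's at the planted centre
  expect_equal(crop$pixels[50:51, 50:51],
               ch$image[round(p$center_y) + (0:1) - 1,
                        round(p$center_x) + (0:1) - 1])
  # circle at the mosaic border: padded, same side length
  border <- crop_droplet(ch$image, c(5, 5), 50)
  expect_equal(dim(border$pixels), c(100L, 100L))
  expect_equal(border$pixels[1, 1], median(ch$image))
})

test_that("all three counters agree with planted truth on clean droplets", {
  cfg <- baseline_config()
  empty <- render_droplet(quiet_scene(seed = 51))$image
  expect_equal(count_cells_hough(empty, cfg), 0L)
  expect_equal(count_cells_mser(empty, cfg), 0L)
  expect_equal(count_cells_morphological(empty, cfg), 0L)
  one <- render_droplet(quiet_scene(n_cells = 1, seed = 52))$image
  expect_equal(count_cells_hough(one, cfg), 1L)
  expect_equal(count_cells_morphological(one, cfg), 1L)
  three <- render_droplet(quiet_scene(n_cells = 3, seed = 57))$image
  expect_equal(count_cells_mser(three, cfg), 3L)
})

test_that("all baselines classify noise-free beadline-free empties as Empty", {
  cfg <- baseline_config()
  imgs <- lapply(1:20, function(i)
    render_droplet(quiet_scene(seed = 500 + i))$image)
  for (method in c("hough", "mser", "morph")) {
    res <- run_baseline(imgs, rep(0L, 20), method, cfg)
    expect_gte(mean(res$pred_label == 0L), 0.99)
  }
})

test_that("MSER proposals outside the droplet rim are discarded", {
  cfg <- baseline_config()
  base <- quiet_scene(n_cells = 2, seed = 53)
  with_frag <- quiet_scene(n_cells = 2, seed = 53)
  with_frag$neighbor_fragments <- 4L
  c1 <- count_cells_mser(render_droplet(base)$image, cfg)
  c2 <- count_cells_mser(render_droplet(with_frag)$image, cfg)
  expect_equal(c1, c2)
})

test_that("the dilatation element merges structures closer than its length", {
  cfg <- baseline_config()
  # two 5-px-radius cells whose edges are ~5 px apart: merged into one
  close_pair <- disc_droplet(centers = rbind(c(55.5, 43), c(55.5, 58)))
  expect_equal(count_cells_morphological(close_pair, cfg), 1L)
  # the same cells ~30 px apart: two objects
  far_pair <- disc_droplet(centers = rbind(c(55.5, 35), c(55.5, 75)))
  expect_equal(count_cells_morphological(far_pair, cfg), 2L)
})
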