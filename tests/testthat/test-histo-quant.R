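solid_image <- function(rgb, h = 4, w = 4) {
  array(rep(rgb, each = h * w), dim = c(h, w, 3))
}

test_that("rgb_to_hsi matches the arccos formulation on primaries", {
  hsi_r <- rgb_to_hsi(solid_image(c(1, 0, 0)))
  expect_equal(hsi_r$hue[1, 1], 0)
  expect_equal(hsi_r$saturation[1, 1], 1)
  expect_equal(hsi_r$intensity[1, 1], 1 / 3)
  expect_true(hsi_r$chromatic[1, 1])

  hsi_g <- rgb_to_hsi(solid_image(c(0, 1, 0)))
  expect_equal(hsi_g$hue[1, 1], 120)
  hsi_b <- rgb_to_hsi(solid_image(c(0, 0, 1)))
  expect_equal(hsi_b$hue[1, 1], 240)

  gray <- rgb_to_hsi(solid_image(c(128, 128, 128) / 255))
  expect_equal(gray$saturation[1, 1], 0)
  expect_equal(gray$hue[1, 1], 0)
  expect_false(gray$chromatic[1, 1])

  # 0..255 integer input is rescaled
  byte <- rgb_to_hsi(solid_image(c(255, 0, 0)))
  expect_equal(byte$intensity[1, 1], 1 / 3)
})

test_that("hue round-trips through the HSI inverse used by the simulator", {
  for (h in c(0, 30, 50, 120, 200, 300)) {
    rgb <- collafluor:::hsi_to_rgb(h, 1, 0.3)
    img <- solid_image(as.vector(rgb), h = 2, w = 2)
    back <- rgb_to_hsi(img)
    expect_equal(back$hue[1, 1], h, tolerance = 1e-6)
    expect_equal(back$intensity[1, 1], 0.3, tolerance = 1e-9)
  }
})

test_that("pixel scores fall off linearly in hue and obey the gates", {
  ref <- reference_color("red", hue_center = 0, hue_tol = 20)
  px <- function(rgb) pixel_scores(rgb_to_hsi(solid_image(rgb)), ref)[1, 1]

  at_center <- collafluor:::hsi_to_rgb(0, 1, 0.3)
  expect_equal(px(as.vector(at_center)), 1.0)
  at_half <- collafluor:::hsi_to_rgb(10, 1, 0.3)    # d = tol/2
  expect_equal(px(as.vector(at_half)), 0.5, tolerance = 1e-6)
  beyond <- collafluor:::hsi_to_rgb(25, 1, 0.3)     # d >= tol
  expect_equal(px(as.vector(beyond)), 0.0)
  # circular distance: hue 350 is 10 degrees from 0
  wrap <- collafluor:::hsi_to_rgb(350, 1, 0.3)
  expect_equal(px(as.vector(wrap)), 0.5, tolerance = 1e-6)

  # saturation gate, intensity gate, achromatic pixels
  low_sat <- collafluor:::hsi_to_rgb(0, 0.1, 0.3)
  expect_equal(px(as.vector(low_sat)), 0.0)
  too_dark <- collafluor:::hsi_to_rgb(0, 1, 0.01)
  expect_equal(px(as.vector(too_dark)), 0.0)
  expect_equal(px(c(0.5, 0.5, 0.5)), 0.0)
})

test_that("quantify_collagen equals the pixel-counting oracle on exact colors", {
  # all-black image scores zero everywhere
  black <- array(0, dim = c(16, 16, 3))
  q0 <- quantify_collagen(black)
  expect_equal(q0$total_collagen_pct, 0)
  expect_equal(sum(q0$scores$area_px), 0L)

  # 30% of pixels exactly at the red reference color, rest black
  sim <- simulate_histology(histology_params(
    width = 128, height = 128, class_fractions = c(red = 0.30)), seed = 2)
  q <- quantify_collagen(sim$image)
  red_row <- q$scores[q$scores$class == "red", ]
  expect_equal(red_row$pct_score, 100 * sim$truth$fraction[1])
  expect_equal(red_row$area_px, sim$truth$n_px[1])
  expect_equal(q$total_collagen_pct, 100 * sim$truth$fraction[1])

  # disjoint 10% red + 5% green: totals add
  sim2 <- simulate_histology(histology_params(
    width = 128, height = 128,
    class_fractions = c(red = 0.10, green = 0.05)), seed = 3)
  q2 <- quantify_collagen(sim2$image)
  expect_equal(q2$total_collagen_pct, 100 * sum(sim2$truth$fraction))

  expect_lte(q2$total_collagen_pct, 100)
  expect_true(all(q2$scores$area_px <= 128 * 128))
})

test_that("scores are invariant to pixel permutations", {
  sim <- simulate_histology(histology_params(
    width = 64, height = 64, class_fractions = c(red = 0.2, green = 0.1)),
    seed = 6)
  img <- sim$image
  perm <- withr::with_seed(1, sample(64 * 64))
  shuffled <- img
  for (ch in 1:3) {
    m <- img[, , ch]
    shuffled[, , ch] <- matrix(m[perm], 64, 64)
  }
  expect_equal(quantify_collagen(shuffled)$scores,
               quantify_collagen(img)$scores)
})

test_that("duplicate class names are rejected and ties follow priority", {
  refs <- list(reference_color("red", 0, 20), reference_color("red", 10, 20))
  img <- solid_image(c(0.9, 0, 0))
  expect_error(quantify_collagen(img, refs), "distinct")

  # exact score tie (identical hue targets under two class names): the
  # pixel is assigned to the higher-priority class (red before yellow)
  refs2 <- list(yellow = reference_color("yellow", 0, 20),
                red = reference_color("red", 0, 20))
  mid <- solid_image(as.vector(collafluor:::hsi_to_rgb(0, 1, 0.3)))
  q <- quantify_collagen(mid, refs2)
  expect_gt(q$scores$score_sum[q$scores$class == "red"], 0)
  expect_equal(q$scores$score_sum[q$scores$class == "yellow"], 0)
})

test_that("pct_score decreases as hue jitter grows", {
  pcts <- vapply(c(0, 5, 10, 20), function(js) {
    sim <- simulate_histology(histology_params(
      width = 128, height = 128, class_fractions = c(red = 0.3),
      hue_jitter_sd = js), seed = 13)
    q <- quantify_collagen(sim$image)
    q$scores$pct_score[q$scores$class == "red"]
  }, numeric(1))
  expect_true(all(diff(pcts) <= 0))
  expect_lt(pcts[4], pcts[1])
})

test_that("qualitative fiber-score records are validated", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("group,day,fiber_color,thick,thin,papillary,mid,deep,horizontal,vertical",
               "laser_treated,5,Yellow,+,+,+,+,_,+,_",
               "laser_treated,10,Red,+,_,+,+,_,+,+"), f)
  rec <- read_qualitative_scores(f)
  expect_equal(nrow(rec), 2L)
  expect_true(rec$thick[1])
  expect_false(rec$deep[1])
  expect_identical(rec$fiber_color, c("Yellow", "Red"))

  f2 <- tempfile(fileext = ".csv")
  writeLines(c("fiber_color,thick", "Blue,+"), f2)
  expect_error(read_qualitative_scores(f2), "unknown fiber color")

  f3 <- tempfile(fileext = ".csv")
  writeLines("fiber_color,thick", f3)
  expect_equal(nrow(read_qualitative_scores(f3)), 0L)
})

test_that("images survive PNG and TIFF round trips byte-identically", {
  sim <- simulate_histology(histology_params(
    width = 32, height = 32, class_fractions = c(red = 0.2, yellow = 0.1)),
    seed = 4)
  fp <- tempfile(fileext = ".png")
  write_image(sim$image, fp)
  expect_equal(read_image(fp), sim$image, tolerance = 0)
  ft <- tempfile(fileext = ".tiff")
  write_image(sim$image, ft)
  expect_equal(read_image(ft), sim$image, tolerance = 1e-7)
})
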