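test_that("ellipse truth matches brute-force pixel-center rasterization", {
  fx <- make_ellipse(center = c(50, 50), axes = c(20, 12), angle = 0,
                     noise_sd = 0, seed = 1)
  # independent per-pixel loop over the ellipse inequality
  cnt <- 0L
  for (yy in 0:99) for (xx in 0:99)
    if (((xx - 50) / 20)^2 + ((yy - 50) / 12)^2 <= 1) cnt <- cnt + 1L
  expect_identical(sum(fx$truth), as.numeric(cnt))
  expect_true(all(fx$truth %in% c(0, 1)))
  expect_true(all(fx$image >= 0 & fx$image <= 1))
})

test_that("degenerate unit-axes ellipse keeps only the unit-radius disc", {
  fx <- make_ellipse(center = c(50, 50), axes = c(1, 1), noise_sd = 0,
                     seed = 1)
  g <- expand.grid(x = 0:99, y = 0:99)
  inside <- (g$x - 50)^2 + (g$y - 50)^2 <= 1
  expect_equal(sum(fx$truth), sum(inside))
})

test_that("occlusion and missing modes corrupt the image but not the truth", {
  clean <- make_ellipse(axes = c(20, 12), mode = "clean", noise_sd = 0,
                        seed = 3)
  occ <- make_ellipse(axes = c(20, 12), mode = "occluded", noise_sd = 0,
                      seed = 3)
  mis <- make_ellipse(axes = c(20, 12), mode = "missing", noise_sd = 0,
                      seed = 3)
  expect_identical(occ$truth, clean$truth)
  expect_identical(mis$truth, clean$truth)
  diffpx <- which(occ$image != clean$image, arr.ind = TRUE)
  # occlusion bar: a vertical strip through the upper half of the ellipse
  expect_true(nrow(diffpx) > 0)
  expect_true(all(abs((diffpx[, 2] - 1) - 50) <= 5))
  expect_true(all((diffpx[, 1] - 1) <= 50))
  expect_true(any(mis$image != clean$image))
})

test_that("ellipse exceeding the canvas is rejected with a diagnostic", {
  expect_error(make_ellipse(center = c(90, 50), axes = c(20, 12)),
               "exceeds")
  expect_error(make_ellipse(axes = c(-3, 5)), "positive")
})

test_that("fish area scales like the square of the similarity factor", {
  big <- make_fish(scale = 1, bend = 0, seed = 2, noise_sd = 0)
  small <- make_fish(scale = 0.5, bend = 0, seed = 2, noise_sd = 0)
  ratio <- sum(small$truth) / sum(big$truth)
  expect_lt(abs(ratio - 0.25), 0.025)
})

test_that("straight fish is mirror-symmetric about its horizontal axis", {
  fx <- make_fish(scale = 1, bend = 0, seed = 2, noise_sd = 0)
  idx <- which(fx$truth == 1, arr.ind = TRUE)
  # reflect each foreground pixel about the body axis row (y = 50)
  refl <- cbind(2 * 51 - idx[, 1], idx[, 2])
  hit <- fx$truth[refl] == 1
  # 1-px rasterization slack: nearly all pixels must have a mirror partner
  expect_gt(mean(hit), 0.97)
})

test_that("distinct fish parameter sets give pairwise-distinct silhouettes", {
  f1 <- make_fish(scale = 0.8, bend = 0, seed = 5)
  f2 <- make_fish(scale = 1.1, bend = 0.15, seed = 5)
  f3 <- make_fish(scale = 1.3, bend = -0.2, seed = 5)
  expect_false(identical(f1$truth, f2$truth))
  expect_false(identical(f1$truth, f3$truth))
  expect_false(identical(f2$truth, f3$truth))
  expect_error(make_fish(scale = 2), "scale")
})

test_that("blob area shrinks monotonically with atrophy", {
  areas <- sapply(c(0, 0.25, 0.5, 0.75, 1), function(a)
    sum(make_hc_blob(atrophy = a, seed = 4)$truth))
  expect_true(all(diff(areas) < 0))
})

test_that("edge-gap suppression weakens the boundary gradient only in the image", {
  sharp <- make_hc_blob(edge_gap_fraction = 0, noise_sd = 0, seed = 4)
  weak <- make_hc_blob(edge_gap_fraction = 0.5, noise_sd = 0, seed = 4)
  full <- make_hc_blob(edge_gap_fraction = 1, noise_sd = 0, seed = 4)
  expect_identical(sharp$truth, weak$truth)
  expect_identical(sharp$truth, full$truth)
  bnd <- which(lbseg:::boundary_pixels(sharp$truth) == 1, arr.ind = TRUE)
  gmag <- function(img) {
    gr <- lbseg:::grad_central(img)
    sqrt(gr$gx^2 + gr$gy^2)
  }
  # fully suppressed boundary: even the strongest edge response drops
  expect_gt(max(gmag(sharp$image)[bnd]), max(gmag(full$image)[bnd]))
  # half-suppressed boundary: the average edge response drops
  expect_gt(mean(gmag(sharp$image)[bnd]), mean(gmag(weak$image)[bnd]))
  # with no gap and no noise the interior is flat
  expect_equal(var(sharp$image[sharp$truth == 1 &
                                 lbseg:::boundary_pixels(sharp$truth) == 0]),
               0)
})

test_that("fixture generation is bit-reproducible under a fixed seed", {
  a <- make_ellipse(axes = c(18, 11), angle = 25, seed = 99)
  b <- make_ellipse(axes = c(18, 11), angle = 25, seed = 99)
  expect_identical(a, b)
  expect_false(identical(a$image,
                         make_ellipse(axes = c(18, 11), angle = 25,
                                      seed = 100)$image))
  f1 <- make_hc_blob(atrophy = 0.3, noise_sd = 0.05, seed = 7)
  f2 <- make_hc_blob(atrophy = 0.3, noise_sd = 0.05, seed = 7)
  expect_identical(f1, f2)
})

test_that("rotation augmentation obeys the count law", {
  fx <- make_ellipse(axes = c(15, 10), seed = 1)
  aug <- augment_rotations(list(fx), 60, 10)
  expect_length(aug$items, 7)
  expect_equal(aug$rotations_deg, seq(0, 60, 10))
  # the training-set arithmetic: 460 base slices x 7 rotations
  expect_equal(460 * (60 / 10 + 1), 3220)
  aug2 <- augment_rotations(list(fx, fx, fx), 40, 20)
  expect_length(aug2$items, 9)
  expect_error(augment_rotations(list(fx), 60, 25), "divide")
})

test_that("zero-span augmentation is the identity", {
  fx <- make_fish(scale = 0.9, seed = 3)
  aug <- augment_rotations(list(fx), 0)
  expect_length(aug$items, 1)
  expect_identical(aug$items[[1]]$image, fx$image)
  expect_identical(aug$items[[1]]$truth, fx$truth)
})

test_that("masks stay binary and images in range after rotation", {
  fx <- make_hc_blob(atrophy = 0.2, noise_sd = 0.05, seed = 8)
  aug <- augment_rotations(list(fx), 60, 10)
  for (it in aug$items) {
    expect_true(all(it$truth %in% c(0, 1)))
    expect_true(all(it$image >= 0 & it$image <= 1))
  }
})

test_that("rotate/unrotate rasterization loss keeps Dice above 0.95", {
  fx <- make_ellipse(axes = c(20, 12), seed = 1)
  for (ang in c(10, 30, 50)) {
    r <- rotate_grid(fx$truth, ang, "nearest")
    back <- rotate_grid(r, -ang, "nearest")
    expect_gte(dice(back, fx$truth), 0.95)
  }
})

test_that("rotation pushing foreground off-canvas is rejected with the index", {
  corner <- make_ellipse(center = c(75, 75), axes = c(20, 6), angle = -45,
                         seed = 1)
  expect_error(augment_rotations(list(corner), 60, 10), "off-canvas")
})

test_that("analytic ellipse angle and raster rotation share one convention", {
  t0 <- make_ellipse(axes = c(20, 12), angle = 0, noise_sd = 0, seed = 1)$truth
  t20 <- make_ellipse(axes = c(20, 12), angle = 20, noise_sd = 0,
                      seed = 1)$truth
  expect_gte(dice(rotate_grid(t0, 20, "nearest"), t20), 0.95)
})
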