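test_that("grayscale conversion applies the luma weights", {
  u <- array(77, c(3, 4, 3))
  expect_equal(to_grayscale(u), matrix(77, 3, 4))

  black <- array(0, c(2, 2, 3))
  expect_equal(to_grayscale(black), matrix(0, 2, 2))

  red <- array(0, c(2, 2, 3)); red[, , 1] <- 255
  expect_equal(to_grayscale(red)[1, 1], 0.299 * 255)

  expect_error(to_grayscale(array(0, c(0, 4, 3))), "empty")
  expect_error(to_grayscale(array(0, c(4, 4, 2))), "H x W x 3")
})

test_that("gaussian blur preserves constants, handles sigma 0, matches direct convolution", {
  m <- matrix(runif(200, 0, 255), 10, 20)
  expect_identical(gaussian_blur(m, 0), m)

  u <- matrix(42, 8, 8)
  expect_equal(gaussian_blur(u, 2.5), u)

  # single bright pixel: center equals the kernel's central weight x 255
  imp <- matrix(0, 11, 11); imp[6, 6] <- 255
  g <- exp(-((-4):4)^2 / 2); g <- g / sum(g)
  expect_equal(gaussian_blur(imp, 1)[6, 6], g[5]^2 * 255)

  # interior and border pixels agree with brute-force 2-D convolution
  set.seed(7)
  m <- matrix(runif(15 * 12, 0, 255), 15, 12)
  b <- gaussian_blur(m, 1.5)
  for (rc in list(c(8, 6), c(1, 1), c(15, 12), c(2, 11))) {
    expect_equal(b[rc[1], rc[2]], brute_blur_at(m, 1.5, rc[1], rc[2]),
                 tolerance = 1e-10)
  }

  expect_error(gaussian_blur(m, -1), "non-negative")
})

test_that("blur preserves mean intensity", {
  set.seed(11)
  m <- matrix(runif(400, 0, 255), 20, 20)
  expect_equal(mean(gaussian_blur(m, 2)), mean(m), tolerance = 0.01)
})

test_that("binarize: fixed threshold and perfectly separable otsu", {
  u <- matrix(10, 5, 5)
  expect_equal(sum(binarize(u, "fixed", 50)), 0)
  expect_error(binarize(u, "fixed"), "threshold")
  expect_error(binarize(u, "fixed", 300), "\\[0, 255\\]")

  two <- matrix(c(rep(0, 40), rep(200, 24)), 8, 8)
  bm <- binarize(two, "otsu")
  expect_identical(bm == 1L, two == 200)
})

test_that("otsu equals exhaustive search over all 256 thresholds", {
  set.seed(3)
  for (k in 1:5) {
    levels <- sample(0:255, 4)
    v <- sample(levels, 500, replace = TRUE, prob = runif(4, 0.1, 1))
    img <- matrix(v, 20, 25)
    expect_equal(otsu_threshold(img), brute_otsu(v))
  }
})

test_that("small-component removal matches flood-fill enumeration and is idempotent", {
  m <- matrix(0L, 20, 30)
  m[3:12, 3:12] <- 1L          # 100 px
  m[15, 20] <- 1L; m[16, 21] <- 1L; m[17, 22] <- 1L  # diagonal 3 px
  expect_identical(remove_small_components(m, 0), m)

  f <- remove_small_components(m, 10)
  expect_equal(foreground_count(f), 100)
  expect_true(all(f[3:12, 3:12] == 1L))

  z <- matrix(0L, 5, 5)
  expect_identical(remove_small_components(z, 10), z)

  set.seed(21)
  r <- matrix(as.integer(runif(30 * 40) < 0.35), 30, 40)
  lab_pkg <- label_components(r)
  lab_ff <- flood_components(r)
  # same partition: component pixel sets agree up to label names
  expect_equal(max(lab_pkg), max(lab_ff))
  key <- paste(lab_pkg, lab_ff)
  expect_equal(length(unique(key[r == 1])), max(lab_pkg))

  for (a in c(2, 5, 9)) {
    f1 <- remove_small_components(r, a)
    expect_identical(remove_small_components(f1, a), f1)
    expect_lte(foreground_count(f1), foreground_count(r))
    sizes <- tabulate(flood_components(f1))
    if (length(sizes)) expect_true(all(sizes >= a))
  }
})

test_that("contour extraction: squares, disks, ordering", {
  sq <- matrix(0L, 20, 20); sq[5:14, 5:14] <- 1L
  cs <- extract_contours(sq)
  expect_length(cs, 1)
  expect_equal(contour_area(cs[[1]]), 100, tolerance = 0.05)

  two <- matrix(0L, 30, 60)
  two[3:22, 3:22] <- 1L       # 400 px
  two[10:14, 40:44] <- 1L     # 25 px
  cs2 <- extract_contours(two)
  expect_length(cs2, 2)
  expect_gt(contour_area(cs2[[1]]), contour_area(cs2[[2]]))

  expect_identical(extract_contours(matrix(0L, 5, 5)), list())

  # disk radius 50: enclosed area within 2% of pi r^2 and of pixel count
  h <- 120; xy <- expand.grid(x = 0:119, y = 0:119)
  d <- matrix(as.integer((xy$x - 60)^2 + (xy$y - 60)^2 <= 50^2), h, h,
              byrow = TRUE)
  cd <- extract_contours(d)
  expect_length(cd, 1)
  expect_equal(contour_area(cd[[1]]), pi * 50^2, tolerance = 0.02)
  expect_equal(contour_area(cd[[1]]), foreground_count(d), tolerance = 0.02)
})

test_that("rasterizing extracted contours reproduces components (IoU >= 0.95)", {
  set.seed(5)
  scene <- render_scene(random_scene(3, seed = 14, noise_sigma = 0))
  gt <- scene$ground_truth
  masks <- c(list(gt$coin_mask), gt$pod_masks)
  for (m in masks) {
    ct <- extract_contours(m)[[1]]
    r <- rasterize_polygon(ct, nrow(m), ncol(m))
    expect_gte(mask_iou(r, m), 0.95)
  }
})

test_that("contour area: exact polygons and triangulation oracle", {
  expect_equal(contour_area(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))), 1)
  expect_equal(contour_area(rbind(c(0, 0), c(4, 0), c(0, 3))), 6)
  expect_error(contour_area(rbind(c(0, 0), c(1, 1))), "3 points")

  # random simple 12-gon (star-convex by construction)
  set.seed(9)
  for (k in 1:5) {
    ang <- sort(runif(12, 0, 2 * pi))
    rad <- runif(12, 1, 10)
    p <- cbind(rad * cos(ang), rad * sin(ang))
    expect_equal(contour_area(p), fan_area(p), tolerance = 1e-12)
  }
})

test_that("contour perimeter: exact polygons and regular 64-gon closed form", {
  expect_equal(contour_perimeter(rbind(c(0, 0), c(10, 0), c(10, 10), c(0, 10))), 40)
  expect_equal(contour_perimeter(rbind(c(0, 0), c(3, 0), c(0, 4))), 12)
  r <- 7.3
  ang <- 2 * pi * (0:63) / 64
  p64 <- cbind(r * cos(ang), r * sin(ang))
  expect_equal(contour_perimeter(p64), 2 * 64 * r * sin(pi / 64))
  expect_equal(contour_perimeter(p64), 2 * pi * r, tolerance = 0.005)
})

test_that("contour invariances: translation, cyclic rotation, scaling, isoperimetry", {
  set.seed(13)
  ang <- sort(runif(10, 0, 2 * pi))
  p <- cbind(10 * cos(ang), 10 * sin(ang)) * runif(10, 0.5, 1)
  a0 <- contour_area(p); l0 <- contour_perimeter(p)

  shift <- sweep(p, 2, c(123, -45), "+")
  expect_equal(contour_area(shift), a0)
  cyc <- p[c(4:10, 1:3), ]
  expect_equal(contour_area(cyc), a0)

  s <- 3.7
  expect_equal(contour_area(p * s), a0 * s^2)
  expect_equal(contour_perimeter(p * s), l0 * s)

  # isoperimetric bound on extracted contours of random blobs
  for (seed in 1:6) {
    set.seed(seed)
    m <- matrix(0L, 40, 40)
    m[10:30, 10:30] <- as.integer(matrix(runif(441), 21) < 0.8)
    m <- remove_small_components(m, 5)
    for (ct in extract_contours(m))
      expect_lte(contour_area(ct), contour_perimeter(ct)^2 / (4 * pi))
  }
})
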