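write_labelme_fixture <- function(path, shapes, h = 100, w = 150) {
  doc <- list(version = "5.0.1",
              shapes = shapes,
              imagePath = "img001.png", imageHeight = h, imageWidth = w)
  writeLines(jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA), path)
  path
}

poly_shape <- function(label, pts) {
  list(label = label, points = lapply(seq_len(nrow(pts)), function(i)
    as.numeric(pts[i, ])), shape_type = "polygon")
}

test_that("labelme reading round-trips polygons and skips other shapes", {
  tri <- rbind(c(0, 0), c(40, 0), c(0, 30))
  quad <- rbind(c(10, 10), c(60, 12), c(55, 45), c(12, 40))
  f <- write_labelme_fixture(tempfile(fileext = ".json"),
                             list(poly_shape("pod", tri),
                                  poly_shape("pod", quad)))
  inst <- read_labelme(f)
  expect_length(inst, 2)
  expect_equal(inst[[1]]$polygon, unname(tri))
  expect_equal(nrow(inst[[2]]$polygon), 4)
  expect_equal(inst[[2]]$label, "pod")

  f0 <- write_labelme_fixture(tempfile(fileext = ".json"), list())
  expect_length(read_labelme(f0), 0)

  mixed <- list(poly_shape("pod", tri),
                list(label = "pt", points = list(c(5, 5)),
                     shape_type = "point"))
  fm <- write_labelme_fixture(tempfile(fileext = ".json"), mixed)
  expect_warning(inst_m <- read_labelme(fm), "non-polygon")
  expect_length(inst_m, 1)

  bad <- tempfile(fileext = ".json"); writeLines("{not json", bad)
  expect_error(read_labelme(bad), "cannot parse")
  nosize <- tempfile(fileext = ".json")
  writeLines('{"shapes": []}', nosize)
  expect_error(read_labelme(nosize), "imageHeight")
})

test_that("COCO conversion: areas, bboxes, deterministic ids, validation", {
  img <- list(path = "a.png", height = 100, width = 150)
  tri <- labeled_instance("pod", rbind(c(0, 0), c(4, 0), c(0, 3)), img)
  doc <- to_coco(list(tri))
  a <- doc$annotations[[1]]
  expect_equal(a$area, 6)
  expect_equal(a$bbox, c(0, 0, 4, 3))
  expect_equal(a$iscrowd, 0L)

  empty <- to_coco(list())
  expect_length(empty$annotations, 0)
  expect_length(empty$images, 0)
  expect_equal(empty$categories[[1]]$name, "pod")

  img2 <- list(path = "b.png", height = 100, width = 150)
  insts <- list(
    labeled_instance("pod", rbind(c(10, 10), c(30, 10), c(30, 20), c(10, 20)), img2),
    tri,
    labeled_instance("pod", rbind(c(50, 50), c(80, 55), c(60, 90)), img))
  doc2 <- to_coco(insts)
  # ids unique, images sorted by file name, every annotation references one
  iids <- vapply(doc2$images, function(i) i$id, numeric(1))
  expect_equal(vapply(doc2$images, function(i) i$file_name, character(1)),
               c("a.png", "b.png"))
  aids <- vapply(doc2$annotations, function(a) a$id, numeric(1))
  expect_equal(sort(aids), seq_along(aids))
  expect_true(all(vapply(doc2$annotations, function(a) a$image_id, numeric(1))
                  %in% iids))
  # per-annotation area matches an independent shoelace evaluation
  for (a in doc2$annotations) {
    poly <- coco_polygon(a)
    expect_equal(a$area, fan_area(poly))
    expect_equal(a$bbox[3], max(poly[, 1]) - min(poly[, 1]))
  }

  expect_error(to_coco(list(labeled_instance("weed", tri$polygon, img))),
               "weed")
})

test_that("labelme -> COCO -> decode preserves vertices and areas exactly", {
  quad <- rbind(c(10.5, 10.25), c(60, 12), c(55, 45.75), c(12, 40))
  f <- write_labelme_fixture(tempfile(fileext = ".json"),
                             list(poly_shape("pod", quad)))
  inst <- read_labelme(f)
  doc <- to_coco(inst)
  p <- tempfile(fileext = ".json")
  write_coco(doc, p)
  back <- read_coco(p)
  poly <- coco_polygon(back$annotations[[1]])
  expect_equal(nrow(poly), nrow(quad))
  expect_equal(poly, unname(quad))
  expect_equal(back$annotations[[1]]$area, contour_area(quad))
})

test_that("prediction loading: thresholds, polygon and RLE decoding", {
  h <- 40; w <- 50
  # polygon-encoded 10x10 square at (5,5)..(14,14) in pixel-center coords
  sq_poly <- c(4.5, 4.5, 14.5, 4.5, 14.5, 14.5, 4.5, 14.5)
  mask <- rect_mask(h, w, 6, 15, 6, 15)
  # uncompressed RLE for the same mask, column-major
  v <- as.integer(mask)
  r <- rle(v)
  counts <- r$lengths
  if (r$values[1] == 1L) counts <- c(0L, counts)
  recs <- list(
    list(image_id = 1, category_id = 1, score = 0.9,
         segmentation = list(sq_poly)),
    list(image_id = 1, category_id = 1, score = 0.4,
         segmentation = list(size = c(h, w), counts = as.list(counts))),
    list(image_id = 1, category_id = 1, score = 0.7,
         segmentation = list(size = c(h, w),
                             counts = encode_rle_string(counts))))
  f <- tempfile(fileext = ".json")
  writeLines(jsonlite::toJSON(recs, auto_unbox = TRUE, digits = NA), f)
  sizes <- list("1" = c(h, w))

  none <- load_predictions(f, sizes, score_threshold = 1.1)
  expect_length(none, 0)

  all3 <- load_predictions(f, sizes, score_threshold = 0)
  expect_length(all3[["1"]]$masks, 3)
  expect_equal(all3[["1"]]$scores, c(0.9, 0.4, 0.7))
  # polygon decode: pixel count equals the polygon area (exact here)
  expect_equal(sum(all3[["1"]]$masks[[1]]), 100)
  expect_identical(all3[["1"]]$masks[[1]], mask)
  # both RLE routes reproduce the mask exactly
  expect_identical(all3[["1"]]$masks[[2]], mask)
  expect_identical(all3[["1"]]$masks[[3]], mask)

  some <- load_predictions(f, sizes, score_threshold = 0.5)
  expect_length(some[["1"]]$masks, 2)

  bad <- tempfile(fileext = ".json")
  writeLines('[{"image_id": 1, "score": 1, "segmentation": 42}]', bad)
  expect_error(load_predictions(bad, sizes), "encoding")
})

test_that("compressed RLE decoding round-trips random masks", {
  set.seed(31)
  for (k in 1:10) {
    m <- matrix(as.integer(runif(30 * 20) < 0.4), 30, 20)
    v <- as.integer(m)
    r <- rle(v)
    counts <- r$lengths
    if (r$values[1] == 1L) counts <- c(0L, counts)
    rle_obj <- list(size = c(30, 20), counts = encode_rle_string(counts))
    expect_identical(podmetrics:::rle_to_mask(rle_obj), m)
  }
})

test_that("dataset splitting is disjoint, sized 9:1 and seed-stable", {
  img <- function(k) list(path = sprintf("im%02d.png", k),
                          height = 50, width = 60)
  insts <- lapply(1:10, function(k)
    labeled_instance("pod", rbind(c(1, 1), c(10, 1), c(5, 8)) + k, img(k)))
  doc <- to_coco(insts)
  sp <- split_dataset(doc, 0.9, seed = 99)
  expect_length(sp$train$images, 9)
  expect_length(sp$val$images, 1)
  tr <- vapply(sp$train$images, function(i) i$file_name, character(1))
  va <- vapply(sp$val$images, function(i) i$file_name, character(1))
  expect_length(intersect(tr, va), 0)
  # annotations follow their images
  expect_length(sp$train$annotations, 9)
  expect_length(sp$val$annotations, 1)

  sp2 <- split_dataset(doc, 0.9, seed = 99)
  expect_identical(sp, sp2)
  sp3 <- split_dataset(doc, 0.9, seed = 100)
  expect_false(identical(vapply(sp3$val$images, function(i) i$file_name,
                                character(1)), va) &&
               identical(vapply(sp3$train$images, function(i) i$file_name,
                                character(1)), tr))

  one <- to_coco(insts[1])
  expect_error(split_dataset(one, 0.9, 1), "at least 2")
  expect_error(split_dataset(doc, 1.2, 1), "train_fraction")
})
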