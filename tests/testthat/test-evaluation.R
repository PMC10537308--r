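test_that("mask IoU counts overlap correctly", {
  a <- rect_mask(20, 20, 3, 12, 3, 12)
  expect_equal(mask_iou(a, a), 1)
  b <- rect_mask(20, 20, 15, 18, 15, 18)
  expect_equal(mask_iou(a, b), 0)
  # two 10x10 squares overlapping in a 5x10 strip
  c1 <- rect_mask(30, 30, 1, 10, 1, 10)
  c2 <- rect_mask(30, 30, 6, 15, 1, 10)
  expect_equal(mask_iou(c1, c2), 1 / 3)
  expect_equal(mask_iou(matrix(0L, 5, 5), matrix(0L, 5, 5)), 0)
  expect_error(mask_iou(a, matrix(0L, 5, 5)), "dimensions")
})

test_that("greedy matching follows scores and IoU, one-to-one", {
  gts <- list(masks = list(rect_mask(20, 30, 2, 10, 2, 10),
                           rect_mask(20, 30, 2, 10, 15, 25)))
  perfect <- list(masks = gts$masks, scores = c(0.8, 0.9))
  m <- match_instances(perfect, gts, 0.5)
  expect_equal(m$gt, c(1L, 2L))
  expect_equal(m$iou, c(1, 1))

  none <- match_instances(list(masks = list(), scores = numeric()), gts, 0.5)
  expect_equal(nrow(none), 0)

  expect_error(match_instances(perfect, gts, 0), "iou_threshold")
})

test_that("3 preds x 2 gts matching equals the enumerated greedy assignment", {
  set.seed(41)
  for (trial in 1:20) {
    gts <- random_toy_instances(2, scored = FALSE)
    preds <- random_toy_instances(3)
    got <- match_instances(preds, gts, 0.3)
    # independent re-derivation: walk preds by score, argmax IoU >= thr
    remaining <- c(TRUE, TRUE)
    want <- rep(NA_integer_, 3)
    for (i in order(-preds$scores, 1:3)) {
      ious <- vapply(1:2, function(g)
        if (remaining[g]) mask_iou(preds$masks[[i]], gts$masks[[g]]) else -1,
        numeric(1))
      if (max(ious) >= 0.3) {
        g <- which.max(ious)
        want[i] <- g; remaining[g] <- FALSE
      }
    }
    expect_identical(got$gt, want)
  }
})

test_that("precision and recall from match counts", {
  gts <- list(masks = list(rect_mask(20, 30, 2, 10, 2, 10),
                           rect_mask(20, 30, 2, 10, 15, 25)))
  perfect <- list(masks = gts$masks, scores = c(0.9, 0.8))
  pr <- precision_recall(match_instances(perfect, gts, 0.5), 2)
  expect_equal(unname(pr), c(1, 1))

  empty <- precision_recall(match_instances(list(masks = list(),
                                                 scores = numeric()),
                                            gts, 0.5), 2)
  expect_equal(unname(empty), c(0, 0))

  # TP = 2, FP = 1, FN = 1
  three <- list(masks = c(gts$masks, list(rect_mask(20, 30, 12, 18, 2, 8))),
                scores = c(0.9, 0.8, 0.7))
  gts3 <- list(masks = c(gts$masks, list(rect_mask(20, 30, 14, 19, 20, 28))))
  pr3 <- precision_recall(match_instances(three, gts3, 0.5), 3)
  expect_equal(unname(pr3), c(2 / 3, 2 / 3))
})

test_that("AP: perfect predictions give 1, misses give hand-computed values", {
  gt_masks <- list(rect_mask(30, 30, 2, 10, 2, 10),
                   rect_mask(30, 30, 15, 25, 15, 25))
  gts <- list(img1 = list(masks = gt_masks))
  perfect <- list(img1 = list(masks = gt_masks, scores = c(0.5, 0.6)))
  for (t in seq(0.5, 0.95, 0.05))
    expect_equal(average_precision(perfect, gts, t), 1)

  # 1 gt, 2 preds: high-scored hit then a miss -> interpolated AP = 1;
  # high-scored miss then a hit -> AP = 0.5 at every recall point
  one_gt <- list(img1 = list(masks = gt_masks[1]))
  miss <- rect_mask(30, 30, 20, 28, 20, 28)
  hit_first <- list(img1 = list(masks = list(gt_masks[[1]], miss),
                                scores = c(0.9, 0.8)))
  expect_equal(average_precision(hit_first, one_gt, 0.5), 1)
  miss_first <- list(img1 = list(masks = list(miss, gt_masks[[1]]),
                                 scores = c(0.9, 0.8)))
  expect_equal(average_precision(miss_first, one_gt, 0.5), 0.5)

  # no predictions but ground truth present -> AP = 0
  expect_equal(average_precision(list(), gts, 0.5), 0)
  # no ground truth anywhere -> absent
  expect_true(is.na(average_precision(perfect,
                                      list(img1 = list(masks = list())), 0.5)))
})

test_that("AP equals the brute-force evaluator on random toy sets", {
  set.seed(43)
  for (trial in 1:60) {
    gts <- list(a = random_toy_instances(sample(0:3, 1), scored = FALSE),
                b = random_toy_instances(sample(0:3, 1), scored = FALSE))
    preds <- list(a = random_toy_instances(sample(0:4, 1)),
                  b = random_toy_instances(sample(0:4, 1)))
    for (t in c(0.5, 0.75))
      expect_equal(average_precision(preds, gts, t), naive_ap(preds, gts, t))
  }
})

test_that("AP is non-increasing in the IoU threshold", {
  set.seed(47)
  for (trial in 1:10) {
    gts <- list(a = random_toy_instances(3, scored = FALSE))
    preds <- list(a = random_toy_instances(4))
    aps <- vapply(seq(0.3, 0.95, 0.05), function(t)
      average_precision(preds, gts, t), numeric(1))
    expect_true(all(diff(aps) <= 1e-12))
  }
})

test_that("injected duplicate false positives never raise AP", {
  set.seed(53)
  for (trial in 1:10) {
    gts <- list(a = random_toy_instances(2, scored = FALSE))
    preds <- list(a = random_toy_instances(3))
    base <- average_precision(preds, gts, 0.5)
    dup <- preds
    dup$a$masks <- c(dup$a$masks, dup$a$masks)
    dup$a$scores <- c(dup$a$scores, dup$a$scores)
    expect_lte(average_precision(dup, gts, 0.5), base + 1e-12)
  }
})

test_that("evaluate fills the report, strata and the Nan convention", {
  # large gt (> 96^2 needs a big canvas); use one large and one small object
  h <- 220; w <- 220
  big <- rect_mask(h, w, 10, 110, 10, 110)      # 101^2 > 96^2
  small <- rect_mask(h, w, 150, 160, 150, 160)  # 11^2 < 32^2
  gts <- list(im = list(masks = list(big, small)))
  preds <- list(im = list(masks = list(big, small), scores = c(0.9, 0.8)))
  rep <- evaluate_instances(preds, gts)
  expect_equal(rep$precision, 1); expect_equal(rep$recall, 1)
  expect_equal(rep$map_50_95, 1)
  expect_equal(unname(rep$ap_by_threshold), rep(1, 10))
  expect_equal(rep$ap_small, 1)
  expect_equal(rep$ap_large, 1)
  expect_true(is.na(rep$ap_medium))   # no medium gt -> Nan convention
  expect_equal(mean(rep$ap_by_threshold), rep$map_50_95)

  out <- capture.output(print(rep))
  expect_true(any(grepl("Nan", out)))

  expect_error(evaluate_instances(list(other = list(masks = list())), gts),
               "missing from ground truth")

  # bbox-level evaluation of the same scene is also perfect
  repb <- evaluate_instances(preds, gts, level = "bbox")
  expect_equal(repb$map_50_95, 1)
})
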