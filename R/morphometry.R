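#' Pod length in pixels (half-perimeter estimate)
#'
#' An elongated pod's length is estimated as half the perimeter of its
#' closed contour. This is exact for a degenerate segment and overestimates
#' a straight pod of centerline length L and width w by about one width
#' (a rectangle gives L + w); the bias is documented rather than corrected.
#'
#' @param c pod `"contour"`.
#' @return length in px.
#' @export
pod_length_px <- function(c) contour_perimeter(c) / 2

#' Pod width in pixels (area over length)
#'
#' Width is the contour area divided by the half-perimeter length, i.e.
#' the mean width of an elongated shape. The isoperimetric inequality
#' (area <= perimeter^2 / (4 pi)) guarantees width <= length / pi, so the
#' derived width is always strictly less than the derived length.
#'
#' @param c pod `"contour"`.
#' @return width in px.
#' @export
pod_width_px <- function(c) {
  len <- pod_length_px(c)
  if (len <= 0) stop("zero-length contour", call. = FALSE)
  contour_area(c) / len
}

#' Measure one pod contour in pixel and physical units
#'
#' Applies the coin-calibrated conversions: `length = length_pixel *
#' diameter_ratio`, `width = width_pixel * diameter_ratio`,
#' `area = area_pixel * area_ratio`.
#'
#' @param c pod `"contour"`.
#' @param scale a `"calibration_scale"` (see [make_scale()]).
#' @param pod_id integer identifier.
#' @return object of class `"pod_measurement"`: list with `pod_id`,
#'   `length_pixel`, `width_pixel`, `area_pixel`, `length`, `width`,
#'   `area` (mm / mm^2) and the `contour`.
#' @export
measure_pod <- function(c, scale, pod_id = 1L) {
  stopifnot(inherits(scale, "calibration_scale"))
  lp <- pod_length_px(c)
  wp <- pod_width_px(c)
  ap <- contour_area(c)
  structure(list(
    pod_id = as.integer(pod_id),
    length_pixel = lp, width_pixel = wp, area_pixel = ap,
    length = lp * scale$diameter_ratio,
    width = wp * scale$diameter_ratio,
    area = ap * scale$area_ratio,
    contour = if (inherits(c, "contour")) c else contour(c)
  ), class = "pod_measurement")
}

#' Pipeline configuration
#'
#' Collects the tunables of the measurement pipeline with their defaults.
#' `min_component_area` is specified at the native 2400 x 1600 capture
#' resolution and rescaled by the processed image's relative pixel area.
#'
#' @param blur_sigma Gaussian blur sigma in px (default 1.5).
#' @param threshold_method `"otsu"` or `"fixed"`.
#' @param threshold fixed threshold in \[0, 255\] (only for `"fixed"`).
#' @param min_component_area noise-removal cutoff in px^2 at 2400 x 1600
#'   (default 150; scaled by image area for other sizes).
#' @param coin_diameter_mm physical coin diameter (default 25).
#' @param circularity_min coin circularity threshold (default 0.8).
#' @param coin_min_area minimum coin area in px^2 (default 500).
#' @return a named list of class `"measure_config"`.
#' @export
measure_config <- function(blur_sigma = 1.5,
                           threshold_method = c("otsu", "fixed"),
                           threshold = NULL,
                           min_component_area = 150,
                           coin_diameter_mm = 25,
                           circularity_min = 0.8,
                           coin_min_area = 500) {
  structure(list(blur_sigma = blur_sigma,
                 threshold_method = match.arg(threshold_method),
                 threshold = threshold,
                 min_component_area = min_component_area,
                 coin_diameter_mm = coin_diameter_mm,
                 circularity_min = circularity_min,
                 coin_min_area = coin_min_area),
            class = "measure_config")
}

#' Measure every pod in an image
#'
#' Full pipeline: grayscale conversion, Gaussian blur, thresholding,
#' pixel-area noise removal, contour extraction, coin identification and
#' calibration, then per-pod measurement of every remaining contour.
#' Pods are numbered left to right by contour centroid x (ties broken by
#' centroid y).
#'
#' @param img H x W x 3 array (or H x W grayscale matrix).
#' @param config a [measure_config()].
#' @return object of class `"pod_measurements"`: list with `scale`
#'   (`"calibration_scale"`), `pods` (list of `"pod_measurement"`) and
#'   `image_size` (c(H, W)). Zero pods is valid and gives an empty list.
#' @export
measure_image <- function(img, config = measure_config()) {
  gray <- to_grayscale(img)
  if (config$blur_sigma > 0) gray <- gaussian_blur(gray, config$blur_sigma)
  mask <- binarize(gray, method = config$threshold_method,
                   threshold = config$threshold)
  min_area <- config$min_component_area *
    (nrow(gray) * ncol(gray)) / (2400 * 1600)
  mask <- remove_small_components(mask, min_area)
  # with automatic thresholding, refine each object's boundary with a
  # local threshold so objects of different brightness are delineated at
  # their own half-intensity level (see refine_contours_local)
  contours <- if (config$threshold_method == "otsu")
    refine_contours_local(gray, mask, margin = ceiling(4 * config$blur_sigma) + 4L)
  else extract_contours(mask)
  coin <- find_coin(contours, config$circularity_min, config$coin_min_area)
  scale <- make_scale(coin_pixel_diameter(coin), contour_area(coin),
                      config$coin_diameter_mm)
  is_coin <- vapply(contours, identical, logical(1), y = coin)
  pods <- contours[!is_coin]
  if (length(pods)) {
    ctr <- t(vapply(pods, contour_centroid, numeric(2)))
    pods <- pods[order(ctr[, 1], ctr[, 2])]
  }
  structure(list(
    scale = scale,
    pods = lapply(seq_along(pods), function(i)
      measure_pod(pods[[i]], scale, pod_id = i)),
    image_size = c(nrow(gray), ncol(gray))
  ), class = "pod_measurements")
}

#' Number of measured pods
#' @param measurements a `"pod_measurements"` object or list of
#'   `"pod_measurement"`.
#' @return integer count.
#' @export
count_pods <- function(measurements) {
  if (inherits(measurements, "pod_measurements"))
    length(measurements$pods)
  else length(measurements)
}

#' @export
as.data.frame.pod_measurements <- function(x, ...) {
  if (length(x$pods) == 0L)
    return(data.frame(pod_id = integer(), length_px = numeric(),
                      width_px = numeric(), area_px = numeric(),
                      length_mm = numeric(), width_mm = numeric(),
                      area_mm2 = numeric()))
  do.call(rbind, lapply(x$pods, function(p)
    data.frame(pod_id = p$pod_id, length_px = p$length_pixel,
               width_px = p$width_pixel, area_px = p$area_pixel,
               length_mm = p$length, width_mm = p$width, area_mm2 = p$area)))
}

#' @export
print.pod_measurements <- function(x, ...) {
  cat(sprintf("%d pod(s); %s\n", length(x$pods), format(x$scale)))
  if (length(x$pods)) print(as.data.frame(x), ...)
  invisible(x)
}

#' Summary statistics of a trait sample
#'
#' Mean, median, min and max are computed on the raw values; the mode is
#' the most frequent value after rounding to `digits` decimals, ties
#' resolved to the smallest value.
#'
#' @param values numeric vector, length >= 1.
#' @param digits decimals used for the mode (default 1, matching the
#'   reporting convention of trait tables in cm).
#' @return list of class `"trait_summary"`: `n`, `mean`, `median`, `mode`,
#'   `min`, `max`.
#' @export
summarize_trait <- function(values, digits = 1) {
  if (length(values) < 1L || !is.numeric(values) || anyNA(values))
    stop("need at least one non-missing value", call. = FALSE)
  r <- round(values, digits)
  tab <- table(r)
  best <- names(tab)[tab == max(tab)]
  structure(list(n = length(values), mean = mean(values),
                 median = median(values),
                 mode = min(as.numeric(best)),
                 min = min(values), max = max(values)),
            class = "trait_summary")
}

#' @export
print.trait_summary <- function(x, ...) {
  cat(sprintf("n=%d mean=%.4g median=%.4g mode=%.4g min=%.4g max=%.4g\n",
              x$n, x$mean, x$median, x$mode, x$min, x$max))
  invisible(x)
}

#' Compare two measurement series by linear regression
#'
#' Ordinary least squares of `y` on `x` (e.g. machine-vision measurements
#' against manual ones), returning slope, intercept and the coefficient of
#' determination.
#'
#' @param x,y numeric vectors of equal length, n >= 2; `x` must not be
#'   constant.
#' @return list of class `"comparison_fit"`: `slope`, `intercept`,
#'   `r_squared`, `n`.
#' @export
compare_measurements <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  if (length(x) < 2L) stop("need at least two paired values", call. = FALSE)
  if (sd(x) == 0) stop("x is constant; regression undefined", call. = FALSE)
  fit <- lm(y ~ x)
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((y - mean(y))^2)
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r_squared = if (ss_tot == 0) 1 else 1 - ss_res / ss_tot,
                 n = length(x)),
            class = "comparison_fit")
}

#' @export
print.comparison_fit <- function(x, ...) {
  cat(sprintf("y = %.4fx %+.5f, r^2 = %.4f (n = %d)\n",
              x$slope, x$intercept, x$r_squared, x$n))
  invisible(x)
}

# --- annotation rendering -------------------------------------------------

# 3x5 bitmap glyphs for measurement labels
.glyphs <- local({
  g <- list(
    "0" = c("111","101","101","101","111"),
    "1" = c("010","110","010","010","111"),
    "2" = c("111","001","111","100","111"),
    "3" = c("111","001","111","001","111"),
    "4" = c("101","101","111","001","001"),
    "5" = c("111","100","111","001","111"),
    "6" = c("111","100","111","101","111"),
    "7" = c("111","001","010","010","010"),
    "8" = c("111","101","111","101","111"),
    "9" = c("111","101","111","001","111"),
    "." = c("000","000","000","000","010"),
    ":" = c("000","010","000","010","000"),
    "L" = c("100","100","100","100","111"),
    "W" = c("101","101","101","111","101"),
    "A" = c("010","101","111","101","101"),
    " " = c("000","000","000","000","000"))
  lapply(g, function(rows) do.call(rbind, lapply(rows, function(r)
    as.integer(strsplit(r, "")[[1]]))))
})

draw_text <- function(img, text, x, y, col = c(255, 255, 0), scale = 2) {
  chars <- strsplit(text, "")[[1]]
  cx <- round(x)
  for (ch in chars) {
    glyph <- .glyphs[[ch]]
    if (!is.null(glyph)) {
      px <- which(glyph == 1L, arr.ind = TRUE)
      for (k in seq_len(nrow(px))) {
        rr <- round(y) + (px[k, 1] - 1L) * scale + seq_len(scale) - 1L
        cc <- cx + (px[k, 2] - 1L) * scale + seq_len(scale) - 1L
        rr <- rr[rr >= 1 & rr <= nrow(img)]
        cc <- cc[cc >= 1 & cc <= ncol(img)]
        if (length(rr) && length(cc)) for (ch2 in 1:3)
          img[rr, cc, ch2] <- col[ch2]
      }
    }
    cx <- cx + 4L * scale
  }
  img
}

#' Render measurements onto a copy of the image
#'
#' Each pod's contour is outlined and its physical length (L), width (W)
#' and area (A) printed near the contour centroid. The input image is not
#' modified.
#'
#' @param img H x W x 3 array.
#' @param measurements a `"pod_measurements"` object (or its `pods` list).
#' @param outline_col,text_col RGB triplets in 0..255.
#' @return annotated H x W x 3 array of the same dimensions.
#' @export
annotate_image <- function(img, measurements,
                           outline_col = c(255, 60, 60),
                           text_col = c(255, 255, 0)) {
  if (is.matrix(img)) img <- array(rep(img, 3), c(dim(img), 3))
  out <- img
  pods <- if (inherits(measurements, "pod_measurements"))
    measurements$pods else measurements
  for (p in pods) {
    pts <- p$contour$points
    rr <- pmin(pmax(round(pts[, 2]) + 1L, 1L), nrow(out))
    cc <- pmin(pmax(round(pts[, 1]) + 1L, 1L), ncol(out))
    for (ch in 1:3) out[cbind(rr, cc, ch)] <- outline_col[ch]
    ctr <- contour_centroid(p$contour)
    lab <- sprintf("L:%.1f W:%.1f A:%.0f", p$length, p$width, p$area)
    out <- draw_text(out, lab, ctr[1] - 4 * 2 * nchar(lab) / 2,
                     ctr[2] - 5, col = text_col)
  }
  out
}
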