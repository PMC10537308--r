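#' Midpoint of two points
#' @param p,q length-2 numeric (x, y).
#' @return coordinate-wise mean, length-2 numeric.
#' @export
midpoint <- function(p, q) (as.numeric(p) + as.numeric(q)) / 2

#' Euclidean distance between two points
#' @param p,q length-2 numeric (x, y).
#' @return distance in the same units as the coordinates.
#' @export
euclidean_distance <- function(p, q) sqrt(sum((as.numeric(p) - as.numeric(q))^2))

#' Order four box corners top-left, top-right, bottom-right, bottom-left
#'
#' Corners are sorted clockwise on screen (ascending `atan2(y - cy, x - cx)`
#' in image coordinates, where y grows downward) around their centroid,
#' starting from the corner with the smallest x + y (ties: smaller y, then
#' smaller x). Edge midpoints (top, bottom, left, right) are the means of
#' the respective corner pairs.
#'
#' @param points 4 x 2 numeric matrix of distinct (x, y) points forming a
#'   convex quadrilateral.
#' @return object of class `"ordered_box"`: list with `corners` (4 x 2
#'   matrix, rows tl/tr/br/bl) and `midpoints` (4 x 2 matrix, rows
#'   top/bottom/left/right).
#' @export
order_box_corners <- function(points) {
  p <- as.matrix(points)
  if (nrow(p) != 4L || ncol(p) != 2L) stop("need exactly 4 (x, y) points", call. = FALSE)
  if (nrow(unique(p)) != 4L) stop("corner points must be distinct", call. = FALSE)
  if (abs(signed_area(p[chull_order(p), , drop = FALSE])) < 1e-9)
    stop("degenerate (collinear) corner points", call. = FALSE)
  ctr <- colMeans(p)
  ang <- atan2(p[, 2] - ctr[2], p[, 1] - ctr[1])
  p <- p[order(ang), , drop = FALSE]
  s <- p[, 1] + p[, 2]
  start <- which(s == min(s))
  if (length(start) > 1L) start <- start[order(p[start, 2], p[start, 1])[1]]
  p <- p[((seq_len(4L) + start - 2L) %% 4L) + 1L, , drop = FALSE]
  rownames(p) <- c("tl", "tr", "br", "bl")
  mids <- rbind(top    = midpoint(p["tl", ], p["tr", ]),
                bottom = midpoint(p["bl", ], p["br", ]),
                left   = midpoint(p["tl", ], p["bl", ]),
                right  = midpoint(p["tr", ], p["br", ]))
  colnames(mids) <- c("x", "y")
  colnames(p) <- c("x", "y")
  structure(list(corners = p, midpoints = mids), class = "ordered_box")
}

chull_order <- function(p) {
  h <- chull(p[, 1], p[, 2])
  h
}

#' Minimum-area rotated bounding rectangle of a point set
#'
#' Rotating-calipers search over the convex hull: the minimum-area
#' enclosing rectangle has one side collinear with a hull edge.
#'
#' @param points N x 2 numeric matrix (N >= 3, not all collinear).
#' @return an `"ordered_box"` (see [order_box_corners()]).
#' @export
min_area_rect <- function(points) {
  p <- as_contour_points(points)
  h <- p[chull(p[, 1], p[, 2]), , drop = FALSE]
  if (nrow(h) < 3L) stop("degenerate point set", call. = FALSE)
  best <- NULL; best_area <- Inf
  for (i in seq_len(nrow(h))) {
    j <- if (i == nrow(h)) 1L else i + 1L
    e <- h[j, ] - h[i, ]
    len <- sqrt(sum(e^2)); if (len == 0) next
    u <- e / len; v <- c(-u[2], u[1])
    ru <- h %*% u; rv <- h %*% v
    a <- (max(ru) - min(ru)) * (max(rv) - min(rv))
    if (a < best_area) {
      best_area <- a
      best <- rbind(min(ru) * u + min(rv) * v,
                    max(ru) * u + min(rv) * v,
                    max(ru) * u + max(rv) * v,
                    min(ru) * u + max(rv) * v)
    }
  }
  order_box_corners(best)
}

#' Locate the reference coin among contours
#'
#' The coin is the near-circular contour closest to the left image margin:
#' among contours with circularity `4*pi*area/perimeter^2 >= circularity_min`
#' and enclosed area `>= min_area` px^2, the one with the smallest centroid
#' x is returned. The scene protocol places the coin at the far left, so
#' the leftmost circular object is unambiguous.
#'
#' @param contours non-empty list of `"contour"` objects.
#' @param circularity_min minimum circularity to qualify (default 0.8).
#' @param min_area minimum enclosed area in px^2 (default 500).
#' @return the coin's `"contour"`.
#' @export
find_coin <- function(contours, circularity_min = 0.8, min_area = 500) {
  if (length(contours) == 0L) stop("no contours supplied", call. = FALSE)
  circ <- vapply(contours, circularity, numeric(1))
  areas <- vapply(contours, contour_area, numeric(1))
  ok <- circ >= circularity_min & areas >= min_area
  if (!any(ok))
    stop(sprintf(
      "no coin found: best circularity %.3f (need >= %.2f at area >= %g px^2)",
      max(circ), circularity_min, min_area), call. = FALSE)
  cx <- vapply(contours, function(c) contour_centroid(c)[1], numeric(1))
  contours[ok][[which.min(cx[ok])]]
}

#' Pixel diameter of the coin contour
#'
#' The coin's minimum-area rotated bounding rectangle is computed, its
#' corners ordered, and the diameter taken as the mean of the two
#' midpoint-to-midpoint distances (top to bottom and left to right) —
#' a rotation-robust estimate of the disk diameter.
#'
#' @param coin the coin `"contour"` (see [find_coin()]).
#' @return diameter in px.
#' @export
coin_pixel_diameter <- function(coin) {
  box <- min_area_rect(coin)
  m <- box$midpoints
  (euclidean_distance(m["top", ], m["bottom", ]) +
    euclidean_distance(m["left", ], m["right", ])) / 2
}

#' Build the pixel-to-physical calibration scale
#'
#' Implements the coin-reference conversion:
#' `diameter_ratio = coin_diameter_true / coin_diameter_pixel` (mm/px) and
#' `area_ratio = coin_area_true / coin_area_pixel` (mm^2/px^2), with the
#' coin's true area taken as `pi * (coin_diameter_true / 2)^2`.
#'
#' @param coin_diameter_pixel measured coin diameter in px.
#' @param coin_area_pixel measured coin area in px^2.
#' @param coin_diameter_true physical coin diameter in mm (default 25, a
#'   one-RMB coin).
#' @return object of class `"calibration_scale"` with fields
#'   `coin_diameter_true`, `coin_diameter_pixel`, `coin_area_true`,
#'   `coin_area_pixel`, `diameter_ratio`, `area_ratio`.
#' @examples
#' make_scale(250, pi * 125^2)  # diameter_ratio 0.1 mm/px
#' @export
make_scale <- function(coin_diameter_pixel, coin_area_pixel,
                       coin_diameter_true = 25) {
  vals <- c(coin_diameter_pixel, coin_area_pixel, coin_diameter_true)
  if (!is.numeric(vals) || any(is.na(vals)) || any(vals <= 0))
    stop("all calibration inputs must be positive numbers", call. = FALSE)
  structure(list(
    coin_diameter_true = coin_diameter_true,
    coin_diameter_pixel = coin_diameter_pixel,
    coin_area_true = pi * (coin_diameter_true / 2)^2,
    coin_area_pixel = coin_area_pixel,
    diameter_ratio = coin_diameter_true / coin_diameter_pixel,
    area_ratio = pi * (coin_diameter_true / 2)^2 / coin_area_pixel
  ), class = "calibration_scale")
}

#' @export
print.calibration_scale <- function(x, ...) {
  cat(sprintf("Calibration: coin %.4g mm = %.4g px\n",
              x$coin_diameter_true, x$coin_diameter_pixel))
  cat(sprintf("  diameter_ratio %.6g mm/px, area_ratio %.6g mm^2/px^2\n",
              x$diameter_ratio, x$area_ratio))
  invisible(x)
}

#' @export
format.calibration_scale <- function(x, ...) {
  sprintf("calibration_scale(%.6g mm/px)", x$diameter_ratio)
}
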