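#' Convert an RGB image to grayscale
#'
#' Luma conversion with the ITU-R BT.601 weights
#' (0.299 R + 0.587 G + 0.114 B), the de-facto convention for
#' machine-vision grayscale conversion.
#'
#' @param img H x W x 3 numeric array, intensities in 0..255 (see package
#'   help for conventions). A plain H x W matrix is returned unchanged.
#' @return H x W numeric matrix of grayscale intensities in \[0, 255\].
#' @examples
#' img <- array(0, c(4, 4, 3)); img[, , 1] <- 255
#' to_grayscale(img)[1, 1]  # 0.299 * 255
#' @export
to_grayscale <- function(img) {
  if (is.matrix(img)) {
    if (length(img) == 0L) stop("empty image", call. = FALSE)
    return(img)
  }
  if (!is.array(img) || length(dim(img)) != 3L || dim(img)[3] != 3L)
    stop("expected an H x W x 3 array", call. = FALSE)
  if (dim(img)[1] < 1L || dim(img)[2] < 1L) stop("empty image", call. = FALSE)
  0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
}

# 1-D Gaussian kernel truncated at `truncate` sigmas, normalized to sum 1.
gaussian_kernel <- function(sigma, truncate = 4) {
  r <- max(1L, as.integer(ceiling(truncate * sigma)))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k / sum(k)
}

# Convolve each column of `m` with kernel `k` (odd length), reflect padding
# (mirror about the edge sample: ... 3 2 | 1 2 3 ... n | n-1 n-2 ...).
conv_cols_reflect <- function(m, k) {
  r <- (length(k) - 1L) %/% 2L
  n <- nrow(m)
  idx <- (1L - r):(n + r)
  idx <- ifelse(idx < 1L, 2L - idx, ifelse(idx > n, 2L * n - idx, idx))
  idx <- pmin(pmax(idx, 1L), n)   # guard for kernels wider than the image
  mp <- m[idx, , drop = FALSE]
  out <- matrix(0, n, ncol(m))
  for (j in seq_along(k))
    out <- out + k[j] * mp[(j - 1L) + seq_len(n), , drop = FALSE]
  out
}

#' Gaussian blur of a grayscale image
#'
#' Separable convolution with a normalized 1-D Gaussian kernel truncated at
#' 4 sigma, using reflect padding at the borders (so a uniform image is a
#' fixed point and the mean intensity is preserved).
#'
#' @param img H x W numeric matrix.
#' @param sigma standard deviation of the kernel in pixels; `sigma = 0`
#'   returns the input unchanged.
#' @return blurred H x W numeric matrix.
#' @export
gaussian_blur <- function(img, sigma = 1.5) {
  if (!is.matrix(img)) stop("expected a grayscale matrix", call. = FALSE)
  if (!is.numeric(sigma) || length(sigma) != 1L || is.na(sigma) || sigma < 0)
    stop("sigma must be a single non-negative number", call. = FALSE)
  if (sigma == 0) return(img)
  k <- gaussian_kernel(sigma)
  t(conv_cols_reflect(t(conv_cols_reflect(img, k)), k))
}

#' Otsu threshold of a grayscale image
#'
#' Exhaustive maximization of the between-class variance over the 256
#' candidate thresholds of the 8-bit histogram (values are rounded and
#' clamped to 0..255 for the histogram). Ties resolve to the smallest
#' threshold.
#'
#' @param img H x W numeric matrix with intensities in \[0, 255\].
#' @return the threshold t; foreground is `img > t`.
#' @export
otsu_threshold <- function(img) {
  v <- pmin(pmax(round(as.numeric(img)), 0), 255)
  h <- as.numeric(tabulate(v + 1L, nbins = 256L))
  n <- sum(h)
  lev <- 0:255
  w0 <- cumsum(h)                      # count with value <= t
  s0 <- cumsum(h * lev)                # intensity sum with value <= t
  w1 <- n - w0
  mu0 <- ifelse(w0 > 0, s0 / w0, 0)
  mu1 <- ifelse(w1 > 0, (s0[256] - s0) / w1, 0)
  bcv <- w0 * w1 * (mu0 - mu1)^2       # between-class variance (scaled)
  lev[which.max(bcv)]
}

#' Binarize a grayscale image
#'
#' A pixel becomes foreground (1) when its intensity is strictly greater
#' than the effective threshold. With `method = "otsu"` the threshold is
#' chosen by [otsu_threshold()]; suited to these scenes, where the dark
#' velvet background makes the histogram strongly bimodal.
#'
#' @param img H x W numeric matrix.
#' @param method `"otsu"` (default) or `"fixed"`.
#' @param threshold required for `method = "fixed"`; a value in \[0, 255\].
#' @return H x W integer 0/1 matrix, with the threshold used attached as
#'   attribute `"threshold"`.
#' @export
binarize <- function(img, method = c("otsu", "fixed"), threshold = NULL) {
  method <- match.arg(method)
  if (method == "fixed") {
    if (is.null(threshold) || !is.numeric(threshold) || length(threshold) != 1L)
      stop("method = \"fixed\" requires a single numeric threshold", call. = FALSE)
    if (threshold < 0 || threshold > 255)
      stop("threshold must lie in [0, 255]", call. = FALSE)
    t <- threshold
  } else {
    t <- otsu_threshold(img)
  }
  m <- matrix(as.integer(img > t), nrow(img), ncol(img))
  attr(m, "threshold") <- t
  m
}

#' Number of foreground pixels in a binary mask
#' @param mask H x W 0/1 matrix.
#' @return integer count of 1-pixels.
#' @export
foreground_count <- function(mask) sum(mask != 0)

#' Label 8-connected foreground components
#'
#' Labelling is delegated to `EBImage::bwlabel()` (4-connected) and
#' diagonally adjacent labels are then merged, giving the package's
#' convention of 8-connected foreground over a 4-connected background.
#'
#' @param mask H x W 0/1 matrix.
#' @return H x W integer matrix; 0 = background, components numbered from 1
#'   in an arbitrary but deterministic order.
#' @export
label_components <- function(mask) {
  if (!any(mask != 0)) return(matrix(0L, nrow(mask), ncol(mask)))
  lab <- t(EBImage::imageData(EBImage::bwlabel(EBImage::Image(t(mask != 0)))))
  lab <- matrix(as.integer(lab), nrow(mask), ncol(mask))
  nl <- max(lab)
  if (nl > 1L) {
    h <- nrow(lab); w <- ncol(lab)
    # diagonal neighbour label pairs (down-right and down-left)
    a <- c(lab[-h, -w], lab[-h, -1])
    b <- c(lab[-1, -1], lab[-1, -w])
    keep <- a > 0L & b > 0L & a != b
    if (any(keep)) {
      parent <- seq_len(nl)
      find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
      pairs <- unique(cbind(a[keep], b[keep]))
      for (i in seq_len(nrow(pairs))) {
        ra <- find(pairs[i, 1]); rb <- find(pairs[i, 2])
        if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
      }
      root <- vapply(seq_len(nl), find, integer(1))
      relab <- match(root, sort(unique(root)))
      lab[lab > 0L] <- relab[lab[lab > 0L]]
    }
  }
  lab
}

#' Remove small foreground components
#'
#' Every 8-connected foreground component with fewer than `min_area` pixels
#' is set to background; nothing else changes. Used to clean up background
#' impurities before contour extraction.
#'
#' @param mask H x W 0/1 matrix.
#' @param min_area minimum component pixel count to keep; `0` keeps all.
#' @return filtered H x W 0/1 integer matrix.
#' @export
remove_small_components <- function(mask, min_area) {
  if (!is.numeric(min_area) || length(min_area) != 1L || is.na(min_area) ||
      min_area < 0)
    stop("min_area must be a single non-negative number", call. = FALSE)
  if (min_area == 0 || !any(mask != 0))
    return(matrix(as.integer(mask != 0), nrow(mask), ncol(mask)))
  lab <- label_components(mask)
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= min_area)
  matrix(as.integer(lab %in% keep), nrow(mask), ncol(mask))
}

#' Construct a contour object
#'
#' A contour is a simple closed polygon of 0-based (x, y) pixel
#' coordinates; the first point is not repeated at the end. Orientation is
#' derived from the signed shoelace area, computed with the standard
#' formula on (x, y) as given (image y grows downward, so `"ccw"` here is
#' clockwise on screen).
#'
#' @param points N x 2 numeric matrix of (x, y) coordinates, N >= 3.
#' @return an object of class `"contour"` with elements `points` and
#'   `orientation` (`"ccw"` or `"cw"`).
#' @export
contour <- function(points) {
  points <- as.matrix(points)
  if (!is.numeric(points) || ncol(points) != 2L || nrow(points) < 3L)
    stop("a contour needs an N x 2 matrix with N >= 3", call. = FALSE)
  if (all(points[1, ] == points[nrow(points), ]))
    points <- points[-nrow(points), , drop = FALSE]
  if (nrow(points) < 3L) stop("a contour needs at least 3 distinct points", call. = FALSE)
  colnames(points) <- c("x", "y")
  structure(list(points = points,
                 orientation = if (signed_area(points) > 0) "ccw" else "cw"),
            class = "contour")
}

signed_area <- function(p) {
  x <- p[, 1]; y <- p[, 2]
  0.5 * sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)
}

as_contour_points <- function(c) {
  if (inherits(c, "contour")) c$points else {
    p <- as.matrix(c)
    if (!is.numeric(p) || ncol(p) != 2L) stop("not a contour", call. = FALSE)
    p
  }
}

#' Polygon area of a contour (shoelace formula)
#'
#' @param c a `"contour"` or an N x 2 coordinate matrix.
#' @return absolute enclosed area in px^2.
#' @export
contour_area <- function(c) {
  p <- as_contour_points(c)
  if (nrow(p) < 3L) stop("a contour needs at least 3 points", call. = FALSE)
  abs(signed_area(p))
}

#' Polygon perimeter of a contour
#'
#' Sum of Euclidean edge lengths, including the closing edge back to the
#' first vertex.
#'
#' @inheritParams contour_area
#' @return perimeter in px.
#' @export
contour_perimeter <- function(c) {
  p <- as_contour_points(c)
  if (nrow(p) < 3L) stop("a contour needs at least 3 points", call. = FALSE)
  q <- rbind(p[-1, , drop = FALSE], p[1, , drop = FALSE])
  sum(sqrt(rowSums((q - p)^2)))
}

#' Area-weighted centroid of a contour polygon
#' @inheritParams contour_area
#' @return length-2 numeric (x, y).
#' @export
contour_centroid <- function(c) {
  p <- as_contour_points(c)
  x <- p[, 1]; y <- p[, 2]
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  cr <- x * y2 - x2 * y
  a <- sum(cr) / 2
  if (abs(a) < 1e-12) return(c(mean(x), mean(y)))
  c(sum((x + x2) * cr), sum((y + y2) * cr)) / (6 * a)
}

#' Circularity of a contour
#'
#' `4 * pi * area / perimeter^2`; 1 for a perfect circle, smaller for
#' elongated shapes.
#'
#' @inheritParams contour_area
#' @return circularity in (0, 1\].
#' @export
circularity <- function(c) {
  4 * pi * contour_area(c) / contour_perimeter(c)^2
}

#' Extract outer contours of a binary mask
#'
#' One outer contour per 8-connected foreground component, traced as the
#' 0.5-level isoline of the mask (marching squares on the pixel-center
#' grid). Vertices therefore sit on pixel-edge midpoints half a pixel
#' outside the foreground centers: a filled axis-aligned n x n square
#' yields a polygon of area n^2 - 0.5, and every foreground pixel center
#' lies strictly inside its component's polygon. Holes are ignored.
#'
#' Vertices are then smoothed with a short circular moving average
#' (`smooth` vertices each side) to suppress the staircase of the pixel
#' lattice, which would otherwise inflate the perimeter of slanted edges
#' by up to ~8%; `smooth = 0` disables this.
#'
#' @param mask H x W 0/1 matrix.
#' @param smooth half-width of the vertex moving-average window
#'   (default 3; shrunk automatically for very short contours).
#' @return list of `"contour"` objects ordered by decreasing enclosed
#'   area; empty list for an empty mask.
#' @export
extract_contours <- function(mask, smooth = 3L) {
  lab <- label_components(mask)
  nl <- max(lab)
  if (nl == 0L) return(list())
  out <- vector("list", nl)
  for (l in seq_len(nl)) {
    ij <- which(lab == l, arr.ind = TRUE)
    r0 <- min(ij[, 1]); r1 <- max(ij[, 1])
    c0 <- min(ij[, 2]); c1 <- max(ij[, 2])
    sub <- matrix(0, r1 - r0 + 3L, c1 - c0 + 3L)  # 1-px zero pad
    sub[cbind(ij[, 1] - r0 + 2L, ij[, 2] - c0 + 2L)] <- 1
    # contourLines: z[i, j] at (x[i], y[j]); our x = column, y = row
    xs <- (c0 - 2L):(c1) ; ys <- (r0 - 2L):(r1)   # 0-based global coords
    cl <- contourLines(x = xs, y = ys, z = t(sub), levels = 0.5)
    if (length(cl) == 0L) next
    areas <- vapply(cl, function(p) abs(signed_area(cbind(p$x, p$y))), numeric(1))
    p <- cl[[which.max(areas)]]               # outer boundary; holes smaller
    pts <- smooth_closed(cbind(p$x, p$y), smooth)
    out[[l]] <- contour(pts)
  }
  out <- out[!vapply(out, is.null, logical(1))]
  out[order(vapply(out, contour_area, numeric(1)), decreasing = TRUE)]
}

# Circular moving average of closed-polygon vertices (window 2k+1),
# rescaled about the centroid so the enclosed area is unchanged (the
# averaging rounds corners, which would otherwise shrink small polygons).
smooth_closed <- function(p, k) {
  n <- nrow(p)
  k <- min(as.integer(k), (n - 3L) %/% 4L)
  if (k <= 0L) return(p)
  a0 <- abs(signed_area(p))
  idx <- outer(seq_len(n), (-k):k, "+")
  idx <- ((idx - 1L) %% n) + 1L
  q <- cbind(rowMeans(matrix(p[idx, 1], n)), rowMeans(matrix(p[idx, 2], n)))
  a1 <- abs(signed_area(q))
  if (a1 <= 0) return(p)
  ctr <- contour_centroid(q)
  sweep(sweep(q, 2, ctr) * sqrt(a0 / a1), 2, ctr, "+")
}

# Per-component contour refinement: a single global threshold sits at the
# half-intensity of the dominant foreground class, so objects of a
# different reflectance (the bright coin among duller pods) get their
# boundary displaced by a fraction of the blur width, and thin objects
# whose edge-ramp pixels dominate their histogram are dilated. Each
# component is re-thresholded at its own half-intensity level: midway
# between the median background and median foreground intensity of its
# padded bounding box (medians are insensitive to the ramp pixels).
# Returns contours ordered by area.
refine_contours_local <- function(gray, mask, margin = 10L) {
  lab <- label_components(mask)
  nl <- max(lab)
  if (nl == 0L) return(list())
  out <- vector("list", nl)
  for (l in seq_len(nl)) {
    ij <- which(lab == l, arr.ind = TRUE)
    r0 <- max(1L, min(ij[, 1]) - margin); r1 <- min(nrow(gray), max(ij[, 1]) + margin)
    c0 <- max(1L, min(ij[, 2]) - margin); c1 <- min(ncol(gray), max(ij[, 2]) + margin)
    patch <- gray[r0:r1, c0:c1, drop = FALSE]
    inpatch <- lab[r0:r1, c0:c1, drop = FALSE] == l
    bg <- patch[!inpatch & mask[r0:r1, c0:c1] == 0]
    t_half <- if (length(bg)) (median(bg) + median(patch[inpatch])) / 2
              else otsu_threshold(patch)
    sub <- matrix(as.integer(patch > t_half), nrow(patch), ncol(patch))
    lab2 <- label_components(sub)
    orig <- cbind(ij[, 1] - r0 + 1L, ij[, 2] - c0 + 1L)
    hits <- lab2[orig]
    hits <- hits[hits > 0L]
    if (!length(hits)) { out[[l]] <- extract_contours(lab == l)[[1]]; next }
    comp <- matrix(as.integer(lab2 == which.max(tabulate(hits))),
                   nrow(sub), ncol(sub))
    ct <- extract_contours(comp)
    if (!length(ct)) { out[[l]] <- extract_contours(lab == l)[[1]]; next }
    pts <- ct[[1]]$points
    pts[, 1] <- pts[, 1] + (c0 - 1L)
    pts[, 2] <- pts[, 2] + (r0 - 1L)
    out[[l]] <- contour(pts)
  }
  out[order(vapply(out, contour_area, numeric(1)), decreasing = TRUE)]
}

#' Rasterize a polygon to a binary mask
#'
#' Scanline even-odd fill: a pixel is foreground when its center lies
#' inside the polygon (edges crossing the scanline counted with the
#' half-open rule).
#'
#' @param c a `"contour"` or N x 2 coordinate matrix (0-based x, y).
#' @param height,width output mask dimensions in pixels.
#' @return H x W 0/1 integer matrix.
#' @export
rasterize_polygon <- function(c, height, width) {
  p <- as_contour_points(c)
  mask <- matrix(0L, height, width)
  x1 <- p[, 1]; y1 <- p[, 2]
  x2 <- c(x1[-1], x1[1]); y2 <- c(y1[-1], y1[1])
  rows <- max(0L, floor(min(y1))):min(height - 1L, ceiling(max(y1)))
  for (y in rows) {
    crosses <- (y1 <= y & y2 > y) | (y2 <= y & y1 > y)
    if (!any(crosses)) next
    xi <- x1[crosses] + (y - y1[crosses]) / (y2[crosses] - y1[crosses]) *
      (x2[crosses] - x1[crosses])
    xi <- sort(xi)
    for (k in seq(1L, length(xi) - 1L, by = 2L)) {
      a <- ceiling(xi[k]); b <- floor(xi[k + 1])
      if (xi[k + 1] == floor(xi[k + 1])) b <- b - 1L  # half-open right edge
      a <- max(a, 0L); b <- min(b, width - 1L)
      if (a <= b) mask[y + 1L, (a:b) + 1L] <- 1L
    }
  }
  mask
}

#' Read an image file as an H x W x 3 array
#'
#' PNG and JPEG are supported (decoded by EBImage). Grayscale files are
#' expanded to three identical channels.
#'
#' @param path file path.
#' @return H x W x 3 numeric array with intensities in 0..255.
#' @export
read_image <- function(path) {
  img <- EBImage::readImage(path)
  d <- EBImage::imageData(img)
  if (length(dim(d)) == 2L) d <- array(rep(d, 3L), c(dim(d), 3L))
  if (dim(d)[3] > 3L) d <- d[, , 1:3, drop = FALSE]   # drop alpha
  round(255 * aperm(d, c(2, 1, 3)))
}

#' Write an image or mask as PNG
#'
#' Arrays are assumed to be in 0..255; binary masks (0/1 matrices) are
#' written as single-channel 0/255 PNG.
#'
#' @param img H x W x 3 array, H x W matrix, or 0/1 mask matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  if (is.matrix(img)) {
    v <- img
    if (all(v %in% c(0, 1))) v <- v * 255
    png::writePNG(v / 255, path)
  } else {
    png::writePNG(aperm(img, c(1, 2, 3)) / 255, path)
  }
  invisible(path)
}

#' Serialize contours to JSON
#'
#' @param contours list of `"contour"` objects.
#' @param path optional file path; when `NULL` the JSON string is returned.
#' @return JSON string (invisibly when written to a file).
#' @export
contours_to_json <- function(contours, path = NULL) {
  doc <- lapply(contours, function(c)
    list(orientation = c$orientation, points = unname(c$points)))
  js <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) { writeLines(js, path); return(invisible(js)) }
  js
}
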