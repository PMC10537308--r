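#' Specify an augmentation
#'
#' Describes one augmentation operation with its parameters and, for
#' stochastic operations, the seed that fully determines it. Geometric
#' operations (`hflip`, `vflip`, `rotate`, `scale`, `crop`, `mosaic`)
#' transform image and polygons by the same map; photometric operations
#' (`noise`, `blur`, `cutout`, `color_jitter`) leave polygons unchanged.
#'
#' Parameters by op: `rotate`: `angle` (degrees); `scale`: `factor`;
#' `crop`: `x, y, w, h` (or `w, h` only, position drawn from the seed);
#' `noise`: `sigma` (default 10); `blur`: `sigma` (default 1.5);
#' `cutout`: `n` (default 3), `size` (fraction of min dimension, default
#' 0.1); `color_jitter`: `brightness`, `contrast`, `saturation` (maximum
#' relative jitter, default 0.2 each).
#'
#' @param op one of `"hflip"`, `"vflip"`, `"rotate"`, `"scale"`, `"crop"`,
#'   `"noise"`, `"blur"`, `"cutout"`, `"color_jitter"`, `"mosaic"`.
#' @param ... op parameters (see Details).
#' @param seed integer; required for stochastic ops.
#' @return object of class `"aug_spec"`.
#' @export
aug_spec <- function(op = c("hflip", "vflip", "rotate", "scale", "crop",
                            "noise", "blur", "cutout", "color_jitter",
                            "mosaic"),
                     ..., seed = NULL) {
  op <- match.arg(op)
  structure(list(op = op, params = list(...), seed = seed),
            class = "aug_spec")
}

normalize_instances <- function(instances) {
  lapply(instances, function(i) {
    if (inherits(i, "labeled_instance")) list(label = i$label, polygon = i$polygon)
    else if (is.matrix(i)) list(label = "pod", polygon = i)
    else list(label = i$label %||% "pod", polygon = as.matrix(i$polygon))
  })
}

with_spec_seed <- function(spec, code) {
  if (is.null(spec$seed)) stop(sprintf(
    "op \"%s\" is stochastic and needs a seed", spec$op), call. = FALSE)
  withr::with_seed(spec$seed, code)
}

clamp255 <- function(x) pmin(pmax(x, 0), 255)

rotate90_cw <- function(img) {
  # (x, y) -> (H - 1 - y, x); per-channel transpose + column reversal
  h <- dim(img)[1]
  apply_channels(img, function(m) t(m)[, h:1, drop = FALSE])
}

apply_channels <- function(img, f) {
  if (is.matrix(img)) return(f(img))
  chs <- lapply(1:3, function(k) f(img[, , k]))
  array(c(chs[[1]], chs[[2]], chs[[3]]), c(dim(chs[[1]]), 3L))
}

# Nearest-neighbour inverse warp: for each output pixel, sample the source
# at the inverse-mapped location (0-based pixel-center coordinates).
warp_nn <- function(img, out_h, out_w, inverse_map, fill = 0) {
  xy <- expand.grid(x = 0:(out_w - 1L), y = 0:(out_h - 1L))
  src <- inverse_map(xy$x, xy$y)
  sx <- round(src[[1]]); sy <- round(src[[2]])
  h <- dim(img)[1]; w <- dim(img)[2]
  ok <- sx >= 0 & sx <= w - 1 & sy >= 0 & sy <= h - 1
  lin_out <- xy$y + 1L + out_h * xy$x             # column-major index
  lin_src <- sy[ok] + 1L + h * sx[ok]
  apply_channels(img, function(m) {
    o <- matrix(fill, out_h, out_w)
    o[lin_out[ok]] <- m[lin_src]
    o
  })
}

# Sutherland-Hodgman clip of polygon to axis-aligned rect [x0,x1]x[y0,y1].
clip_polygon_rect <- function(p, x0, y0, x1, y1) {
  clip_half <- function(p, inside, intersect) {
    n <- nrow(p); if (n == 0L) return(p)
    out <- list()
    for (i in seq_len(n)) {
      a <- p[i, ]; b <- p[if (i == n) 1L else i + 1L, ]
      ia <- inside(a); ib <- inside(b)
      if (ia) out[[length(out) + 1L]] <- a
      if (xor(ia, ib)) out[[length(out) + 1L]] <- intersect(a, b)
    }
    if (length(out)) do.call(rbind, out) else matrix(numeric(0), 0, 2)
  }
  ix <- function(a, b, val, coord) {
    t <- (val - a[coord]) / (b[coord] - a[coord])
    a + t * (b - a)
  }
  p <- clip_half(p, function(q) q[1] >= x0, function(a, b) ix(a, b, x0, 1))
  p <- clip_half(p, function(q) q[1] <= x1, function(a, b) ix(a, b, x1, 1))
  p <- clip_half(p, function(q) q[2] >= y0, function(a, b) ix(a, b, y0, 2))
  p <- clip_half(p, function(q) q[2] <= y1, function(a, b) ix(a, b, y1, 2))
  p
}

#' Apply an augmentation to an image and its polygon annotations
#'
#' The image and every polygon are transformed by the same geometric map;
#' photometric ops leave the polygons untouched. With a seed in the spec,
#' repeated application reproduces the output bit for bit. A crop that
#' reduces an instance below 20% of its original polygon area drops the
#' instance (a message reports the count).
#'
#' @param img H x W x 3 array (or grayscale matrix). For `op = "mosaic"`,
#'   a list of exactly four images.
#' @param instances list of polygon annotations (`"labeled_instance"`
#'   objects, N x 2 matrices, or `list(label, polygon)`); for mosaic, a
#'   list of four such lists parallel to the images.
#' @param spec an [aug_spec()].
#' @param min_visible minimum surviving polygon-area fraction after a crop
#'   (default 0.2).
#' @return `list(image = <array>, instances = <list of list(label,
#'   polygon)>)`.
#' @export
apply_augmentation <- function(img, instances, spec, min_visible = 0.2) {
  stopifnot(inherits(spec, "aug_spec"))
  if (spec$op == "mosaic") return(mosaic_augment(img, instances))
  inst <- normalize_instances(instances)
  h <- dim(img)[1]; w <- dim(img)[2]
  map_polys <- function(f) lapply(inst, function(i) {
    i$polygon <- f(i$polygon); i
  })
  p <- spec$params
  switch(spec$op,
    hflip = {
      img <- apply_channels(img, function(m) m[, w:1, drop = FALSE])
      inst <- map_polys(function(q) { q[, 1] <- (w - 1) - q[, 1]; q })
    },
    vflip = {
      img <- apply_channels(img, function(m) m[h:1, , drop = FALSE])
      inst <- map_polys(function(q) { q[, 2] <- (h - 1) - q[, 2]; q })
    },
    rotate = {
      ang <- p$angle %||% 90
      k <- (ang / 90) %% 4
      if (abs(k - round(k)) < 1e-12) {
        for (r in seq_len(round(k) %% 4)) {
          hh <- dim(img)[1]
          img <- rotate90_cw(img)
          inst <- map_polys(function(q)
            cbind((hh - 1) - q[, 2], q[, 1]))
        }
      } else {
        th <- ang * pi / 180
        R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
        cx <- (w - 1) / 2; cy <- (h - 1) / 2
        crn <- cbind(c(0, w - 1, 0, w - 1), c(0, 0, h - 1, h - 1))
        rc <- sweep(crn, 2, c(cx, cy)) %*% t(R)
        ox <- -min(rc[, 1]); oy <- -min(rc[, 2])
        out_w <- ceiling(max(rc[, 1]) + ox) + 1L
        out_h <- ceiling(max(rc[, 2]) + oy) + 1L
        Ri <- t(R)   # inverse of a rotation
        img <- warp_nn(img, out_h, out_w, function(x, y) {
          s <- cbind(x - ox, y - oy) %*% t(Ri)
          list(s[, 1] + cx, s[, 2] + cy)
        })
        inst <- map_polys(function(q) {
          s <- sweep(q, 2, c(cx, cy)) %*% t(R)
          cbind(s[, 1] + ox, s[, 2] + oy)
        })
      }
    },
    scale = {
      s <- p$factor %||% 1
      out_h <- max(1L, round(h * s)); out_w <- max(1L, round(w * s))
      img <- warp_nn(img, out_h, out_w,
                     function(x, y) list((x + 0.5) / s - 0.5,
                                         (y + 0.5) / s - 0.5))
      inst <- map_polys(function(q) (q + 0.5) * s - 0.5)
    },
    crop = {
      cw <- p$w %||% floor(w / 2); ch <- p$h %||% floor(h / 2)
      if (is.null(p$x)) {
        xy <- with_spec_seed(spec, c(sample.int(w - cw + 1L, 1L) - 1L,
                                     sample.int(h - ch + 1L, 1L) - 1L))
        cx0 <- xy[1]; cy0 <- xy[2]
      } else { cx0 <- p$x; cy0 <- p$y }
      img <- apply_channels(img, function(m)
        m[cy0 + seq_len(ch), cx0 + seq_len(cw), drop = FALSE])
      kept <- list(); dropped <- 0L
      for (i in inst) {
        a0 <- contour_area(i$polygon)
        q <- clip_polygon_rect(i$polygon, cx0 - 0.5, cy0 - 0.5,
                               cx0 + cw - 0.5, cy0 + ch - 0.5)
        if (nrow(q) >= 3L && contour_area(q) >= min_visible * a0) {
          q[, 1] <- q[, 1] - cx0; q[, 2] <- q[, 2] - cy0
          i$polygon <- q
          kept[[length(kept) + 1L]] <- i
        } else dropped <- dropped + 1L
      }
      if (dropped > 0L)
        message(sprintf("crop dropped %d instance(s) below %.0f%% visibility",
                        dropped, 100 * min_visible))
      inst <- kept
    },
    noise = {
      sg <- p$sigma %||% 10
      img <- with_spec_seed(spec, {
        n <- array(rnorm(length(img), 0, sg), dim(img))
        clamp255(round(img + n))
      })
    },
    blur = {
      img <- apply_channels(img, function(m)
        gaussian_blur(m, p$sigma %||% 1.5))
    },
    cutout = {
      n_rect <- p$n %||% 3L
      frac <- p$size %||% 0.1
      img <- with_spec_seed(spec, {
        sz <- max(1L, round(frac * min(h, w)))
        for (k in seq_len(n_rect)) {
          x0 <- sample.int(max(1L, w - sz + 1L), 1L)
          y0 <- sample.int(max(1L, h - sz + 1L), 1L)
          img <- apply_channels(img, function(m) {
            m[y0 + seq_len(sz) - 1L, x0 + seq_len(sz) - 1L] <- 0
            m
          })
        }
        img
      })
    },
    color_jitter = {
      img <- with_spec_seed(spec, {
        b <- runif(1, 1 - (p$brightness %||% 0.2), 1 + (p$brightness %||% 0.2))
        cc <- runif(1, 1 - (p$contrast %||% 0.2), 1 + (p$contrast %||% 0.2))
        ss <- runif(1, 1 - (p$saturation %||% 0.2), 1 + (p$saturation %||% 0.2))
        x <- img * b
        x <- (x - mean(x)) * cc + mean(x)
        if (!is.matrix(x)) {
          gray <- to_grayscale(x)
          for (k in 1:3) x[, , k] <- gray + ss * (x[, , k] - gray)
        }
        clamp255(round(x))
      })
    }
  )
  list(image = img, instances = inst)
}

#' Mosaic four annotated images into one
#'
#' The four tiles are arranged in a 2 x 2 grid (row-major input order);
#' every polygon is shifted by its tile's origin. Unequal tile sizes are
#' allowed; gaps are zero-filled.
#'
#' @param imgs list of four H x W x 3 arrays.
#' @param instances_list list of four instance lists (see
#'   [apply_augmentation()]).
#' @return `list(image, instances, origins)` where `origins` is a 4 x 2
#'   matrix of tile (x, y) offsets.
#' @export
mosaic_augment <- function(imgs, instances_list) {
  if (length(imgs) != 4L) stop("mosaic requires exactly 4 images", call. = FALSE)
  hs <- vapply(imgs, function(i) dim(i)[1], numeric(1))
  ws <- vapply(imgs, function(i) dim(i)[2], numeric(1))
  col_x <- max(ws[1], ws[3])                 # left column width
  row_y <- max(hs[1], hs[2])                 # top row height
  W <- col_x + max(ws[2], ws[4])
  H <- row_y + max(hs[3], hs[4])
  origins <- rbind(c(0, 0), c(col_x, 0), c(0, row_y), c(col_x, row_y))
  canvas <- array(0, c(H, W, 3))
  out_inst <- list()
  for (t in 1:4) {
    im <- imgs[[t]]
    if (is.matrix(im)) im <- array(rep(im, 3), c(dim(im), 3))
    ox <- origins[t, 1]; oy <- origins[t, 2]
    canvas[oy + seq_len(hs[t]), ox + seq_len(ws[t]), ] <- im
    for (i in normalize_instances(instances_list[[t]])) {
      i$polygon[, 1] <- i$polygon[, 1] + ox
      i$polygon[, 2] <- i$polygon[, 2] + oy
      out_inst[[length(out_inst) + 1L]] <- i
    }
  }
  list(image = canvas, instances = out_inst, origins = origins)
}
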