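#' Specify a synthetic pod
#'
#' Pods are modelled as constant-width tubes around a centerline: a
#' rectangle (straight centerline, square ends), a capsule (straight
#' centerline, round caps) or a bent tube around a parabolic arc with
#' round caps. Physical dimensions are in mm; the placement (`center`,
#' px) and `orientation` position the pod on the canvas at render time.
#'
#' @param length_mm centerline (arc) length.
#' @param half_width_mm half the pod width; must satisfy
#'   `length_mm > 2 * half_width_mm`.
#' @param center length-2 (x, y) in px.
#' @param orientation radians; 0 lays the pod along +x.
#' @param shape `"capsule"`, `"rect"` or `"bent"`.
#' @param curvature for `"bent"`: maximum centerline deviation from the
#'   chord as a fraction of the chord length (default 0.08).
#' @return object of class `"pod_spec"` with the analytic `true_area_mm2`
#'   (`L * 2h` for rectangles, `L * 2h + pi * h^2` for round-capped
#'   tubes).
#' @export
pod_spec <- function(length_mm, half_width_mm, center, orientation = 0,
                     shape = c("capsule", "rect", "bent"), curvature = 0.08) {
  shape <- match.arg(shape)
  if (!(length_mm > 2 * half_width_mm))
    stop("length must exceed the pod width", call. = FALSE)
  area <- if (shape == "rect") length_mm * 2 * half_width_mm
          else length_mm * 2 * half_width_mm + pi * half_width_mm^2
  structure(list(length_mm = length_mm, half_width_mm = half_width_mm,
                 center = as.numeric(center), orientation = orientation,
                 shape = shape,
                 curvature = if (shape == "bent") curvature else 0,
                 true_area_mm2 = area),
            class = "pod_spec")
}

#' Specify a synthetic scene
#'
#' Emulates the imaging protocol: a near-black background, one bright
#' coin disk at the left margin (centroid x constrained to the left
#' quarter of the canvas) and elongated pods at intermediate intensity.
#'
#' @param pods list of [pod_spec()] objects.
#' @param height,width canvas size in px.
#' @param mm_per_px physical sampling (default 0.2 mm/px, i.e. a 25 mm
#'   coin spans 125 px).
#' @param coin_center length-2 (x, y) px; must satisfy x < width / 4.
#' @param coin_diameter_mm physical coin diameter (default 25).
#' @param background,pod_intensity,coin_intensity 8-bit intensities
#'   (defaults 15 / 150 / 230).
#' @param noise_sigma additive Gaussian noise sd (default 5; 0 disables).
#' @param seed integer driving the noise.
#' @return object of class `"scene_spec"`.
#' @export
scene_spec <- function(pods = list(), height = 800, width = 1200,
                       mm_per_px = 0.2, coin_center = NULL,
                       coin_diameter_mm = 25, background = 15,
                       pod_intensity = 150, coin_intensity = 230,
                       noise_sigma = 5, seed = 1L) {
  r_px <- coin_diameter_mm / 2 / mm_per_px
  if (is.null(coin_center)) coin_center <- c(r_px + 15, height / 2)
  if (coin_center[1] >= width / 4)
    stop("coin must sit in the left quarter of the canvas", call. = FALSE)
  structure(list(pods = pods, height = height, width = width,
                 mm_per_px = mm_per_px, coin_center = as.numeric(coin_center),
                 coin_diameter_mm = coin_diameter_mm,
                 background = background, pod_intensity = pod_intensity,
                 coin_intensity = coin_intensity, noise_sigma = noise_sigma,
                 seed = as.integer(seed)),
            class = "scene_spec")
}

# Centerline polyline of a pod in px, global coordinates. For bent pods
# the parabolic chord is solved so that the arc length equals the
# requested centerline length.
pod_centerline <- function(pod, mm_per_px, n = 80) {
  L <- pod$length_mm / mm_per_px
  if (pod$shape != "bent" || pod$curvature == 0) {
    t <- seq(-0.5, 0.5, length.out = 2)
    local <- cbind(t * L, 0)
  } else {
    arc_of_chord <- function(c_len) {
      t <- seq(-0.5, 0.5, length.out = n + 1)
      p <- cbind(t * c_len, pod$curvature * c_len * (1 - (2 * t)^2))
      sum(sqrt(rowSums(diff(p)^2)))
    }
    c_len <- stats::uniroot(function(c) arc_of_chord(c) - L,
                            c(L / 2, L), tol = 1e-8)$root
    t <- seq(-0.5, 0.5, length.out = n + 1)
    local <- cbind(t * c_len, pod$curvature * c_len * (1 - (2 * t)^2))
    local[, 2] <- local[, 2] - mean(range(local[, 2]))
  }
  th <- pod$orientation
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  sweep(local %*% t(R), 2, pod$center, "+")
}

# Squared distance from points (px, py) to segment a-b.
dist2_seg <- function(px, py, a, b) {
  dx <- b[1] - a[1]; dy <- b[2] - a[2]
  l2 <- dx^2 + dy^2
  t <- if (l2 == 0) rep(0, length(px)) else
    pmin(pmax(((px - a[1]) * dx + (py - a[2]) * dy) / l2, 0), 1)
  (px - (a[1] + t * dx))^2 + (py - (a[2] + t * dy))^2
}

# Rasterize one pod spec to a full-canvas 0/1 mask.
pod_mask <- function(pod, spec) {
  h_px <- pod$half_width_mm / spec$mm_per_px
  cl <- pod_centerline(pod, spec$mm_per_px)
  x0 <- max(0L, floor(min(cl[, 1]) - h_px - 2))
  x1 <- min(spec$width - 1L, ceiling(max(cl[, 1]) + h_px + 2))
  y0 <- max(0L, floor(min(cl[, 2]) - h_px - 2))
  y1 <- min(spec$height - 1L, ceiling(max(cl[, 2]) + h_px + 2))
  xs <- x0:x1; ys <- y0:y1
  px <- rep(xs, each = length(ys)); py <- rep(ys, times = length(xs))
  if (pod$shape == "rect") {
    th <- pod$orientation
    u <- (px - pod$center[1]) * cos(th) + (py - pod$center[2]) * sin(th)
    v <- -(px - pod$center[1]) * sin(th) + (py - pod$center[2]) * cos(th)
    L <- pod$length_mm / spec$mm_per_px
    inside <- abs(u) <= L / 2 & abs(v) <= h_px
  } else {
    d2 <- rep(Inf, length(px))
    for (i in seq_len(nrow(cl) - 1L))
      d2 <- pmin(d2, dist2_seg(px, py, cl[i, ], cl[i + 1L, ]))
    inside <- d2 <= h_px^2
  }
  mask <- matrix(0L, spec$height, spec$width)
  mask[cbind(py[inside] + 1L, px[inside] + 1L)] <- 1L
  mask
}

coin_mask <- function(spec) {
  r <- spec$coin_diameter_mm / 2 / spec$mm_per_px
  x0 <- max(0L, floor(spec$coin_center[1] - r - 2))
  x1 <- min(spec$width - 1L, ceiling(spec$coin_center[1] + r + 2))
  y0 <- max(0L, floor(spec$coin_center[2] - r - 2))
  y1 <- min(spec$height - 1L, ceiling(spec$coin_center[2] + r + 2))
  xs <- x0:x1; ys <- y0:y1
  px <- rep(xs, each = length(ys)); py <- rep(ys, times = length(xs))
  inside <- (px - spec$coin_center[1])^2 + (py - spec$coin_center[2])^2 <= r^2
  mask <- matrix(0L, spec$height, spec$width)
  mask[cbind(py[inside] + 1L, px[inside] + 1L)] <- 1L
  mask
}

#' Render a synthetic scene with exact ground truth
#'
#' Deterministic for a given spec (the spec's seed drives the noise).
#' Ground truth masks are exact by construction; per-pod truth carries the
#' physical centerline length, width (2 x half-width) and analytic area in
#' mm and their pixel equivalents.
#'
#' @param spec a [scene_spec()].
#' @return list of class `"scene"`: `image` (H x W x 3 array),
#'   `ground_truth` — a list with `coin_mask`, `pod_masks`,
#'   `coin_pixel_diameter`, `mm_per_px` and data.frame `pods`
#'   (`length_mm`, `width_mm`, `area_mm2`, `length_px`, `width_px`,
#'   `area_px2`, `shape`, `expected_length_mm` — the half-perimeter value
#'   the measurement pipeline should report).
#' @export
render_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  cmask <- coin_mask(spec)
  pmasks <- lapply(spec$pods, pod_mask, spec = spec)
  occ <- cmask
  for (m in pmasks) {
    if (any(occ + m > 1L)) stop("overlapping objects in scene spec", call. = FALSE)
    occ <- occ + m
  }
  gray <- matrix(spec$background, spec$height, spec$width)
  for (m in pmasks) gray[m == 1L] <- spec$pod_intensity
  gray[cmask == 1L] <- spec$coin_intensity
  if (spec$noise_sigma > 0)
    gray <- withr::with_seed(spec$seed,
      pmin(pmax(round(gray + rnorm(length(gray), 0, spec$noise_sigma)), 0), 255))
  img <- array(rep(gray, 3), c(spec$height, spec$width, 3))
  pods_df <- if (length(spec$pods)) do.call(rbind, lapply(spec$pods, function(p) {
    w <- 2 * p$half_width_mm
    exp_len <- if (p$shape == "rect") p$length_mm + w
               else p$length_mm + pi * p$half_width_mm
    data.frame(length_mm = p$length_mm, width_mm = w,
               area_mm2 = p$true_area_mm2,
               length_px = p$length_mm / spec$mm_per_px,
               width_px = w / spec$mm_per_px,
               area_px2 = p$true_area_mm2 / spec$mm_per_px^2,
               shape = p$shape, expected_length_mm = exp_len)
  })) else data.frame()
  structure(list(
    image = img,
    ground_truth = list(coin_mask = cmask, pod_masks = pmasks,
                        coin_pixel_diameter = spec$coin_diameter_mm / spec$mm_per_px,
                        mm_per_px = spec$mm_per_px, pods = pods_df),
    spec = spec
  ), class = "scene")
}

#' Draw a random scene specification
#'
#' Rejection-samples non-overlapping pod placements on the canvas, to the
#' right of the coin zone. Pod centerline lengths are uniform on
#' 4.7–15.1 cm and full widths uniform on 0.2–0.5 cm, the trait ranges
#' observed for dried rapeseed pods; orientations stay within ±15 degrees
#' of horizontal, as pods are laid out lengthwise.
#'
#' @param n_pods number of pods (>= 0).
#' @param seed integer; the spec is a pure function of the arguments.
#' @param shapes candidate shapes sampled per pod (default capsule/bent).
#' @param mm_per_px,height,width,noise_sigma forwarded to [scene_spec()].
#' @param max_attempts placement attempts per pod before giving up.
#' @return a `"scene_spec"`.
#' @export
random_scene <- function(n_pods, seed = 1L,
                         shapes = c("capsule", "bent"),
                         mm_per_px = 0.2, height = 800, width = 1200,
                         noise_sigma = 5, max_attempts = 2000L) {
  stopifnot(n_pods >= 0)
  withr::with_seed(seed, {
    r_px <- 25 / 2 / mm_per_px
    coin_center <- c(r_px + 15, runif(1, r_px + 10, height - r_px - 10))
    zone_x0 <- coin_center[1] + r_px + 20   # pods right of the coin
    pods <- list()
    polylines <- list()
    halfw_px <- numeric(0)
    for (k in seq_len(n_pods)) {
      placed <- FALSE
      for (a in seq_len(max_attempts)) {
        len <- runif(1, 47, 151)            # mm
        hw <- runif(1, 1, 2.5)              # mm (full width 2-5 mm)
        shape <- sample(shapes, 1)
        th <- runif(1, -15, 15) * pi / 180
        L_px <- len / mm_per_px; h_px <- hw / mm_per_px
        cx <- runif(1, zone_x0 + L_px / 2 * abs(cos(th)) + h_px + 5,
                    width - L_px / 2 * abs(cos(th)) - h_px - 5)
        cy <- runif(1, L_px / 2 * abs(sin(th)) + h_px + 15,
                    height - L_px / 2 * abs(sin(th)) - h_px - 15)
        if (!is.finite(cx) || !is.finite(cy) || cx <= 0) next
        cand <- pod_spec(len, hw, c(cx, cy), th, shape)
        cl <- pod_centerline(cand, mm_per_px, n = 60)
        ok <- all(cl[, 1] > zone_x0 + h_px, cl[, 1] < width - h_px - 2,
                  cl[, 2] > h_px + 2, cl[, 2] < height - h_px - 2)
        if (ok && length(polylines)) {
          for (j in seq_along(polylines)) {
            d2 <- min_polyline_dist2(cl, polylines[[j]])
            if (sqrt(d2) <= h_px + halfw_px[j] + 10) { ok <- FALSE; break }
          }
        }
        if (ok) {
          pods[[k]] <- cand
          polylines[[k]] <- cl
          halfw_px <- c(halfw_px, h_px)
          placed <- TRUE
          break
        }
      }
      if (!placed)
        stop(sprintf("could not place pod %d of %d; try fewer pods", k, n_pods),
             call. = FALSE)
    }
    scene_spec(pods, height = height, width = width, mm_per_px = mm_per_px,
               coin_center = coin_center, noise_sigma = noise_sigma,
               seed = seed)
  })
}

# min squared distance between two polylines: vertices of each against
# segments of the other (error bounded by half the vertex spacing, which
# the placement margin absorbs), plus an explicit crossing test so that
# intersecting straight segments report distance 0
min_polyline_dist2 <- function(a, b) {
  d2 <- Inf
  for (i in seq_len(nrow(b) - 1L))
    d2 <- min(d2, min(dist2_seg(a[, 1], a[, 2], b[i, ], b[i + 1L, ])))
  for (i in seq_len(nrow(a) - 1L))
    d2 <- min(d2, min(dist2_seg(b[, 1], b[, 2], a[i, ], a[i + 1L, ])))
  if (d2 > 0) {
    cross <- function(o, p, q)
      (p[1] - o[1]) * (q[2] - o[2]) - (p[2] - o[2]) * (q[1] - o[1])
    for (i in seq_len(nrow(a) - 1L)) for (j in seq_len(nrow(b) - 1L)) {
      d1 <- cross(a[i, ], a[i + 1L, ], b[j, ])
      e1 <- cross(a[i, ], a[i + 1L, ], b[j + 1L, ])
      d3 <- cross(b[j, ], b[j + 1L, ], a[i, ])
      e3 <- cross(b[j, ], b[j + 1L, ], a[i + 1L, ])
      if (d1 * e1 < 0 && d3 * e3 < 0) return(0)
    }
  }
  d2
}

#' Export scene ground truth as annotations
#'
#' Traces each ground-truth mask's outer contour and emits either a
#' Labelme-dialect document or a COCO instances document (categories
#' `"coin"`, `"pod"`), so the annotation tooling can be exercised against
#' scenes with known truth.
#'
#' @param scene a rendered `"scene"` (from [render_scene()]).
#' @param format `"labelme"` or `"coco"`.
#' @param image_path file name recorded in the document.
#' @param include_coin include the coin as an annotated instance.
#' @return for `"labelme"`, a nested list in the Labelme dialect; for
#'   `"coco"`, a `"coco_doc"`.
#' @export
export_annotations <- function(scene, format = c("labelme", "coco"),
                               image_path = "scene.png",
                               include_coin = TRUE) {
  format <- match.arg(format)
  gt <- scene$ground_truth
  h <- dim(scene$image)[1]; w <- dim(scene$image)[2]
  img <- list(path = image_path, height = h, width = w)
  inst <- list()
  if (include_coin) {
    cc <- extract_contours(gt$coin_mask)
    inst[[1]] <- labeled_instance("coin", cc[[1]]$points, img)
  }
  for (m in gt$pod_masks) {
    pc <- extract_contours(m)
    inst[[length(inst) + 1L]] <- labeled_instance("pod", pc[[1]]$points, img)
  }
  if (format == "coco") return(to_coco(inst, categories = c("coin", "pod")))
  list(version = "5.0.1", flags = setNames(list(), character(0)),
       shapes = lapply(inst, function(i)
         list(label = i$label,
              points = lapply(seq_len(nrow(i$polygon)), function(r)
                as.numeric(i$polygon[r, ])),
              group_id = NULL, shape_type = "polygon",
              flags = setNames(list(), character(0)))),
       imagePath = image_path, imageData = NULL,
       imageHeight = h, imageWidth = w)
}

#' Write a scene to disk
#'
#' Writes the rendered PNG, a ground-truth JSON (per-pod true dimensions
#' and the coin's pixel diameter) and, optionally, Labelme and/or COCO
#' annotation files.
#'
#' @param scene a `"scene"`.
#' @param out_dir output directory (created if needed).
#' @param name base file name (default `"scene"`).
#' @param labelme,coco also write annotation documents.
#' @return named character vector of the files written, invisibly.
#' @export
write_scene <- function(scene, out_dir, name = "scene",
                        labelme = FALSE, coco = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- c(image = file.path(out_dir, paste0(name, ".png")))
  write_image(scene$image, files[["image"]])
  gt <- scene$ground_truth
  files[["truth"]] <- file.path(out_dir, paste0(name, "_truth.json"))
  writeLines(jsonlite::toJSON(list(
    coin_pixel_diameter = gt$coin_pixel_diameter,
    mm_per_px = gt$mm_per_px, pods = gt$pods),
    auto_unbox = TRUE, digits = NA, dataframe = "rows"), files[["truth"]])
  if (labelme) {
    files[["labelme"]] <- file.path(out_dir, paste0(name, "_labelme.json"))
    writeLines(jsonlite::toJSON(
      export_annotations(scene, "labelme", paste0(name, ".png")),
      auto_unbox = TRUE, digits = NA, null = "null"), files[["labelme"]])
  }
  if (coco) {
    files[["coco"]] <- file.path(out_dir, paste0(name, "_coco.json"))
    write_coco(export_annotations(scene, "coco", paste0(name, ".png")),
               files[["coco"]])
  }
  invisible(files)
}
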