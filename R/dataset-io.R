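#' Construct a labeled polygon instance
#'
#' @param label category name.
#' @param polygon N x 2 matrix of (x, y) image coordinates, N >= 3.
#' @param image list with `path`, `height`, `width` of the source image.
#' @return object of class `"labeled_instance"`.
#' @export
labeled_instance <- function(label, polygon, image) {
  polygon <- as.matrix(polygon)
  if (nrow(polygon) < 3L) stop("polygon needs >= 3 points", call. = FALSE)
  stopifnot(is.character(label), !is.null(image$height), !is.null(image$width))
  # clip to image bounds
  polygon[, 1] <- pmin(pmax(polygon[, 1], 0), image$width - 1)
  polygon[, 2] <- pmin(pmax(polygon[, 2], 0), image$height - 1)
  structure(list(label = label, polygon = unname(polygon), image = image),
            class = "labeled_instance")
}

#' Read a Labelme annotation file
#'
#' Parses the Labelme JSON dialect; each polygon shape becomes one
#' [labeled_instance()]. Shapes of other types are skipped with a warning.
#'
#' @param path Labelme JSON file.
#' @return list of `"labeled_instance"` objects.
#' @export
read_labelme <- function(path) {
  doc <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e)
                    stop(sprintf("cannot parse %s: %s", path, conditionMessage(e)),
                         call. = FALSE))
  if (is.null(doc$imageHeight) || is.null(doc$imageWidth))
    stop(sprintf("%s: missing imageHeight/imageWidth", path), call. = FALSE)
  img <- list(path = doc$imagePath %||% basename(path),
              height = doc$imageHeight, width = doc$imageWidth)
  shapes <- doc$shapes %||% list()
  skipped <- 0L
  out <- list()
  for (s in shapes) {
    if (!identical(s$shape_type %||% "polygon", "polygon")) {
      skipped <- skipped + 1L
      next
    }
    pts <- do.call(rbind, lapply(s$points, function(p) c(p[[1]], p[[2]])))
    out[[length(out) + 1L]] <- labeled_instance(s$label, pts, img)
  }
  if (skipped > 0L)
    warning(sprintf("%s: skipped %d non-polygon shape(s)", path, skipped),
            call. = FALSE)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Convert labeled instances to a COCO instances document
#'
#' Instances are grouped by source image; image and annotation ids are
#' assigned deterministically (images sorted by file name, annotations in
#' polygon order within each image). Each annotation carries the polygon
#' as a flat coordinate list, its tight axis-aligned bbox (x, y, w, h),
#' its shoelace area and `iscrowd = 0`.
#'
#' @param instances list of `"labeled_instance"` objects.
#' @param categories character vector of category names; ids are assigned
#'   in the given order starting at 1. Default: category `"pod"`.
#' @return COCO document as a nested list (class `"coco_doc"`).
#' @export
to_coco <- function(instances, categories = "pod") {
  labs <- vapply(instances, function(i) i$label, character(1))
  unknown <- setdiff(unique(labs), categories)
  if (length(instances) && length(unknown))
    stop("labels not in categories: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  paths <- vapply(instances, function(i) i$image$path, character(1))
  upaths <- sort(unique(paths))
  images <- lapply(seq_along(upaths), function(k) {
    inst <- instances[[match(upaths[k], paths)]]
    list(id = k, file_name = upaths[k],
         height = inst$image$height, width = inst$image$width)
  })
  anns <- list(); aid <- 0L
  for (k in seq_along(upaths)) {
    for (i in which(paths == upaths[k])) {
      aid <- aid + 1L
      poly <- instances[[i]]$polygon
      anns[[aid]] <- list(
        id = aid, image_id = k,
        category_id = match(labs[i], categories),
        segmentation = list(as.numeric(t(poly))),
        bbox = c(min(poly[, 1]), min(poly[, 2]),
                 max(poly[, 1]) - min(poly[, 1]),
                 max(poly[, 2]) - min(poly[, 2])),
        area = contour_area(poly),
        iscrowd = 0L)
    }
  }
  structure(list(
    images = images,
    annotations = anns,
    categories = lapply(seq_along(categories), function(k)
      list(id = k, name = categories[k], supercategory = "plant"))
  ), class = "coco_doc")
}

#' Write / read a COCO document as JSON
#' @param doc a `"coco_doc"` (nested list).
#' @param path JSON file path.
#' @return `write_coco`: `path` invisibly; `read_coco`: a `"coco_doc"`.
#' @export
write_coco <- function(doc, path) {
  writeLines(jsonlite::toJSON(unclass(doc), auto_unbox = TRUE, digits = NA),
             path)
  invisible(path)
}

#' @rdname write_coco
#' @export
read_coco <- function(path) {
  structure(jsonlite::fromJSON(path, simplifyVector = FALSE),
            class = "coco_doc")
}

#' Extract the polygon of a COCO annotation as an N x 2 matrix
#' @param ann one element of a COCO document's `annotations` list.
#' @return N x 2 matrix (first polygon part).
#' @export
coco_polygon <- function(ann) {
  seg <- ann$segmentation[[1]]
  matrix(unlist(seg), ncol = 2, byrow = TRUE)
}

# Decode the compressed COCO run-length string into integer counts.
decode_rle_string <- function(s) {
  codes <- utf8ToInt(s) - 48L
  cnts <- numeric(0)
  i <- 1L
  while (i <= length(codes)) {
    x <- 0; k <- 0L; more <- TRUE
    while (more) {
      c <- codes[i]; i <- i + 1L
      x <- x + (c %% 32) * 32^k
      more <- c >= 32L
      k <- k + 1L
      if (!more && (c %% 32) >= 16L) x <- x - 32^k
    }
    if (length(cnts) > 2L) x <- x + cnts[length(cnts) - 1L]
    cnts <- c(cnts, x)
  }
  cnts
}

# COCO RLE (counts + size, column-major) to a binary mask matrix.
rle_to_mask <- function(rle) {
  h <- rle$size[[1]]; w <- rle$size[[2]]
  counts <- rle$counts
  if (is.character(counts)) counts <- decode_rle_string(counts)
  counts <- as.numeric(unlist(counts))
  vals <- rep(rep_len(c(0L, 1L), length(counts)), counts)
  if (length(vals) != h * w)
    stop("RLE counts do not match mask size", call. = FALSE)
  matrix(vals, nrow = h, ncol = w)   # column-major fill = COCO convention
}

#' Load external instance-segmentation predictions
#'
#' Reads a COCO results JSON (a flat list of scored detections with
#' polygon or run-length-encoded segmentations) and decodes each record to
#' a binary mask. Polygon segmentations need the image sizes, supplied
#' either via `image_sizes` or a ground-truth `"coco_doc"`.
#'
#' @param path COCO results JSON file.
#' @param image_sizes named list `image_id -> c(height, width)`, or a
#'   `"coco_doc"` whose `images` table supplies the sizes.
#' @param score_threshold keep detections with `score >= score_threshold`.
#' @return named list per image id: `list(masks = <list of H x W 0/1
#'   matrices>, scores = <numeric>, category_ids = <integer>)`.
#' @export
load_predictions <- function(path, image_sizes, score_threshold = 0) {
  recs <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (inherits(image_sizes, "coco_doc"))
    image_sizes <- setNames(
      lapply(image_sizes$images, function(im) c(im$height, im$width)),
      vapply(image_sizes$images, function(im) as.character(im$id), character(1)))
  out <- list()
  for (r in recs) {
    if ((r$score %||% 1) < score_threshold) next
    iid <- as.character(r$image_id)
    seg <- r$segmentation
    if (is.list(seg) && !is.null(seg$counts)) {
      mask <- rle_to_mask(seg)
    } else if (is.list(seg)) {
      sz <- image_sizes[[iid]]
      if (is.null(sz)) stop("no image size for image_id ", iid, call. = FALSE)
      mask <- matrix(0L, sz[1], sz[2])
      for (part in seg) {
        poly <- matrix(unlist(part), ncol = 2, byrow = TRUE)
        mask <- pmax(mask, rasterize_polygon(poly, sz[1], sz[2]))
      }
    } else {
      stop("unknown segmentation encoding in ", path, call. = FALSE)
    }
    if (is.null(out[[iid]]))
      out[[iid]] <- list(masks = list(), scores = numeric(),
                         category_ids = integer())
    out[[iid]]$masks[[length(out[[iid]]$masks) + 1L]] <- mask
    out[[iid]]$scores <- c(out[[iid]]$scores, r$score %||% 1)
    out[[iid]]$category_ids <- c(out[[iid]]$category_ids,
                                 as.integer(r$category_id %||% 1L))
  }
  out
}

#' Split a COCO dataset into training and validation parts
#'
#' Image-level split: images are shuffled with the given seed and the
#' first `ceiling(n * train_fraction)` go to the training document; no
#' image appears in both. Annotations follow their images.
#'
#' @param doc a `"coco_doc"`.
#' @param train_fraction in (0, 1); default 0.9 (a 9:1 split).
#' @param seed integer seed for the shuffle.
#' @return list with elements `train` and `val`, both `"coco_doc"`.
#' @export
split_dataset <- function(doc, train_fraction = 0.9, seed = 1L) {
  n <- length(doc$images)
  if (n < 2L) stop("need at least 2 images to split", call. = FALSE)
  if (!(train_fraction > 0 && train_fraction < 1))
    stop("train_fraction must lie in (0, 1)", call. = FALSE)
  perm <- withr::with_seed(seed, sample.int(n))
  n_train <- ceiling(n * train_fraction)
  take <- function(idx) {
    ids <- vapply(doc$images[idx], function(im) im$id, numeric(1))
    structure(list(
      images = doc$images[idx],
      annotations = Filter(function(a) a$image_id %in% ids, doc$annotations),
      categories = doc$categories), class = "coco_doc")
  }
  list(train = take(sort(perm[seq_len(n_train)])),
       val = take(sort(perm[-seq_len(n_train)])))
}
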