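run_config_defaults <- function() list(
  blur_sigma = 1.5,
  threshold_method = "otsu",
  threshold = NULL,
  min_component_area = 150,
  coin_diameter_mm = 25,
  circularity_min = 0.8,
  coin_min_area = 500,
  eval_iou_thresholds = seq(0.5, 0.95, by = 0.05),
  score_threshold = 0,
  report_cm = FALSE,
  seed = 1L,
  out_dir = "."
)

#' Build a run configuration
#'
#' Collects every tunable of the measurement and evaluation workflows.
#' Unknown keys are rejected. Values from a config file can be merged via
#' [read_run_config()]; explicit arguments always win.
#'
#' @param ... named overrides of the defaults: `blur_sigma` (1.5 px),
#'   `threshold_method` ("otsu"), `threshold` (NULL), `min_component_area`
#'   (150 px^2 at 2400 x 1600), `coin_diameter_mm` (25), `circularity_min`
#'   (0.8), `coin_min_area` (500 px^2), `eval_iou_thresholds`
#'   (0.50–0.95 by 0.05), `score_threshold` (0), `report_cm` (FALSE:
#'   measurement CSV in mm; TRUE adds cm columns), `seed` (1),
#'   `out_dir` (".").
#' @param base optional list of values (e.g. from a config file) applied
#'   before `...`.
#' @return named list of class `"run_config"`.
#' @export
run_config <- function(..., base = NULL) {
  cfg <- run_config_defaults()
  apply_over <- function(cfg, over) {
    unknown <- setdiff(names(over), names(cfg))
    if (length(unknown))
      stop("unknown config keys: ", paste(unknown, collapse = ", "),
           call. = FALSE)
    cfg[names(over)] <- over
    cfg
  }
  if (!is.null(base)) cfg <- apply_over(cfg, base)
  cfg <- apply_over(cfg, list(...))
  structure(cfg, class = "run_config")
}

#' Read a run configuration file
#'
#' YAML (or JSON) file of flat key-value pairs; returns a list suitable
#' for `run_config(base = ...)`.
#'
#' @param path config file.
#' @return named list.
#' @export
read_run_config <- function(path) {
  if (grepl("[.]json$", path)) jsonlite::fromJSON(path)
  else yaml::read_yaml(path)
}

as_measure_config <- function(cfg) {
  measure_config(blur_sigma = cfg$blur_sigma,
                 threshold_method = cfg$threshold_method,
                 threshold = cfg$threshold,
                 min_component_area = cfg$min_component_area,
                 coin_diameter_mm = cfg$coin_diameter_mm,
                 circularity_min = cfg$circularity_min,
                 coin_min_area = cfg$coin_min_area)
}

#' Measure a batch of images
#'
#' Runs the full measurement pipeline over each image, writing
#' `measurements.csv` (one row per pod), `summary.json` (per-image pod
#' count, calibration and trait summaries) and, optionally, annotated
#' PNGs next to the outputs. A per-image failure (e.g. no detectable
#' coin) is recorded and the remaining images are still processed.
#'
#' @param paths character vector of image files.
#' @param config a [run_config()].
#' @param annotate write `<name>_annotated.png` per image.
#' @return invisibly, `list(measurements = <data.frame>, failures =
#'   <named character>, files = <paths written>)`; attribute `"status"`
#'   is 0 on full success, 1 when any image failed.
#' @export
run_measure <- function(paths, config = run_config(), annotate = FALSE) {
  if (length(paths) < 1L) stop("no input images given", call. = FALSE)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  mcfg <- as_measure_config(config)
  rows <- list(); summaries <- list(); failures <- character(0)
  files <- character(0)
  for (p in paths) {
    res <- tryCatch(measure_image(read_image(p), mcfg), error = identity)
    if (inherits(res, "error")) {
      failures[basename(p)] <- conditionMessage(res)
      message(sprintf("FAILED %s: %s", basename(p), conditionMessage(res)))
      next
    }
    df <- as.data.frame(res)
    if (nrow(df)) df <- cbind(image = basename(p), df)
    rows[[p]] <- df
    lens <- vapply(res$pods, function(q) q$length, numeric(1))
    wids <- vapply(res$pods, function(q) q$width, numeric(1))
    summaries[[basename(p)]] <- list(
      pod_count = count_pods(res),
      calibration = unclass(res$scale),
      length_mm = if (length(lens)) unclass(summarize_trait(lens)) else NULL,
      width_mm = if (length(wids)) unclass(summarize_trait(wids)) else NULL)
    if (annotate) {
      f <- file.path(config$out_dir,
                     paste0(tools::file_path_sans_ext(basename(p)),
                            "_annotated.png"))
      write_image(annotate_image(read_image(p), res), f)
      files <- c(files, f)
    }
  }
  all_rows <- if (length(rows)) do.call(rbind, rows) else data.frame()
  rownames(all_rows) <- NULL
  if (isTRUE(config$report_cm) && nrow(all_rows)) {
    all_rows$length_cm <- all_rows$length_mm / 10
    all_rows$width_cm <- all_rows$width_mm / 10
  }
  csv <- file.path(config$out_dir, "measurements.csv")
  write.csv(all_rows, csv, row.names = FALSE)
  js <- file.path(config$out_dir, "summary.json")
  writeLines(jsonlite::toJSON(list(images = summaries,
                                   failures = as.list(failures)),
                              auto_unbox = TRUE, digits = NA), js)
  out <- list(measurements = all_rows, failures = failures,
              files = c(csv, js, files))
  attr(out, "status") <- if (length(failures)) 1L else 0L
  invisible(out)
}

# Rasterize every annotation of a COCO doc into per-image mask sets.
coco_to_masks <- function(doc) {
  sizes <- lapply(doc$images, function(im) c(im$height, im$width))
  names(sizes) <- vapply(doc$images, function(im) as.character(im$id),
                         character(1))
  out <- lapply(sizes, function(s) list(masks = list()))
  for (a in doc$annotations) {
    iid <- as.character(a$image_id)
    s <- sizes[[iid]]
    mask <- matrix(0L, s[1], s[2])
    for (part in a$segmentation) {
      poly <- matrix(unlist(part), ncol = 2, byrow = TRUE)
      mask <- pmax(mask, rasterize_polygon(poly, s[1], s[2]))
    }
    out[[iid]]$masks[[length(out[[iid]]$masks) + 1L]] <- mask
  }
  out
}

#' Evaluate predictions against a COCO ground truth
#'
#' Reads a COCO instances document (ground truth) and a COCO results
#' document (predictions), rasterizes both, and computes the full metric
#' suite at mask level (and bbox level on the masks' bounding boxes).
#' Prints the report table and optionally writes it as JSON.
#'
#' @param gt_path COCO instances JSON.
#' @param pred_path COCO results JSON.
#' @param config a [run_config()].
#' @param write_json write `eval_report.json` under `config$out_dir`.
#' @return invisibly, `list(mask = <eval_report>, bbox = <eval_report>)`.
#' @export
run_evaluate <- function(gt_path, pred_path, config = run_config(),
                         write_json = TRUE) {
  gt_doc <- read_coco(gt_path)
  gts <- coco_to_masks(gt_doc)
  preds <- load_predictions(pred_path, gt_doc, config$score_threshold)
  missing <- setdiff(names(preds), names(gts))
  if (length(missing))
    stop("predictions reference unknown image ids: ",
         paste(missing, collapse = ", "), call. = FALSE)
  rep_mask <- evaluate_instances(preds, gts, config$eval_iou_thresholds,
                                 level = "mask")
  rep_bbox <- evaluate_instances(preds, gts, config$eval_iou_thresholds,
                                 level = "bbox")
  print(rep_mask); print(rep_bbox)
  if (write_json) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    eval_report_json(rep_mask, file.path(config$out_dir, "eval_mask.json"))
    eval_report_json(rep_bbox, file.path(config$out_dir, "eval_bbox.json"))
  }
  invisible(list(mask = rep_mask, bbox = rep_bbox))
}
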