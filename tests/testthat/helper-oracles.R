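# Independent oracles used across the suite. Each reimplements the checked
# quantity by a different route (brute force, enumeration, closed form).

# Polygon area by fan triangulation from the first vertex.
fan_area <- function(p) {
  a <- 0
  for (i in 2:(nrow(p) - 1L)) {
    v1 <- p[i, ] - p[1, ]; v2 <- p[i + 1L, ] - p[1, ]
    a <- a + (v1[1] * v2[2] - v1[2] * v2[1]) / 2
  }
  abs(a)
}

# Otsu by explicit two-class scan over all 256 thresholds.
brute_otsu <- function(values) {
  v <- pmin(pmax(round(values), 0), 255)
  best_t <- 0; best_v <- -Inf
  for (t in 0:255) {
    bg <- v[v <= t]; fg <- v[v > t]
    if (!length(bg) || !length(fg)) next
    bcv <- length(bg) * length(fg) * (mean(bg) - mean(fg))^2
    if (bcv > best_v) { best_v <- bcv; best_t <- t }
  }
  best_t
}

# Direct 2-D convolution with a full Gaussian kernel, mirror padding.
brute_blur_at <- function(img, sigma, row, col) {
  r <- ceiling(4 * sigma)
  g <- exp(-((-r):r)^2 / (2 * sigma^2)); g <- g / sum(g)
  K <- outer(g, g)
  acc <- 0
  n <- nrow(img); m <- ncol(img)
  for (dy in (-r):r) for (dx in (-r):r) {
    y <- row + dy; x <- col + dx
    if (y < 1) y <- 2 - y; if (y > n) y <- 2 * n - y
    if (x < 1) x <- 2 - x; if (x > m) x <- 2 * m - x
    y <- min(max(y, 1), n); x <- min(max(x, 1), m)
    acc <- acc + K[dy + r + 1, dx + r + 1] * img[y, x]
  }
  acc
}

# Connected components by explicit stack-based flood fill (8-connected).
flood_components <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  nextl <- 0L
  for (start in which(mask != 0)) {
    if (lab[start] != 0L) next
    nextl <- nextl + 1L
    stack <- start
    while (length(stack)) {
      s <- stack[length(stack)]; stack <- stack[-length(stack)]
      if (lab[s] != 0L) next
      lab[s] <- nextl
      r <- (s - 1L) %% nrow(mask) + 1L
      cc <- (s - 1L) %/% nrow(mask) + 1L
      for (dr in -1:1) for (dc in -1:1) {
        rr <- r + dr; c2 <- cc + dc
        if (rr >= 1 && rr <= nrow(mask) && c2 >= 1 && c2 <= ncol(mask) &&
            mask[rr, c2] != 0 && lab[rr, c2] == 0L)
          stack <- c(stack, (c2 - 1L) * nrow(mask) + rr)
      }
    }
  }
  lab
}

# Naive AP evaluator: explicit greedy matching per image, raw PR points,
# 101-recall-point interpolation by direct scan.
naive_ap <- function(preds, gts, thr) {
  det <- NULL
  for (im in names(gts)) {
    p <- preds[[im]]
    if (!is.null(p) && length(p$masks))
      det <- rbind(det, data.frame(img = im, idx = seq_along(p$masks),
                                   score = p$scores))
  }
  n_gt <- sum(vapply(gts, function(g) length(g$masks), numeric(1)))
  if (n_gt == 0) return(NA_real_)
  if (is.null(det)) return(0)
  det <- det[order(-det$score, match(det$img, names(gts)), det$idx), ]
  used <- lapply(gts, function(g) rep(FALSE, length(g$masks)))
  is_tp <- logical(nrow(det))
  iou <- function(a, b) {
    u <- sum(a | b); if (u == 0) 0 else sum(a & b) / u
  }
  for (r in seq_len(nrow(det))) {
    im <- det$img[r]
    dm <- preds[[im]]$masks[[det$idx[r]]] != 0
    best <- 0; bg <- 0
    for (j in seq_along(gts[[im]]$masks)) {
      if (used[[im]][j]) next
      v <- iou(dm, gts[[im]]$masks[[j]] != 0)
      if (v >= thr && v > best) { best <- v; bg <- j }
    }
    if (bg > 0) { used[[im]][bg] <- TRUE; is_tp[r] <- TRUE }
  }
  prec <- cumsum(is_tp) / seq_along(is_tp)
  rec <- cumsum(is_tp) / n_gt
  total <- 0
  for (rc in seq(0, 1, by = 0.01)) {
    p_at <- 0
    for (i in seq_along(rec)) if (rec[i] >= rc && prec[i] > p_at) p_at <- prec[i]
    total <- total + p_at
  }
  total / 101
}

# Random toy instance set on a small canvas: axis-aligned rectangles.
random_toy_instances <- function(n, h = 24, w = 24, scored = TRUE) {
  masks <- list(); scores <- numeric(0)
  for (i in seq_len(n)) {
    x0 <- sample.int(w - 6, 1); y0 <- sample.int(h - 6, 1)
    ww <- sample(3:6, 1); hh <- sample(3:6, 1)
    m <- matrix(0L, h, w)
    m[y0:min(h, y0 + hh), x0:min(w, x0 + ww)] <- 1L
    masks[[i]] <- m
    scores <- c(scores, round(runif(1), 3))
  }
  if (scored) list(masks = masks, scores = scores) else list(masks = masks)
}

# COCO compressed-RLE encoder (inverse of the package's decoder, written
# from the format definition: delta-coded counts in 5-bit little-endian
# chunks, continuation bit 0x20, char offset 48).
encode_rle_string <- function(counts) {
  out <- integer(0)
  for (i in seq_along(counts)) {
    x <- counts[i]
    if (i > 3) x <- x - counts[i - 2]
    more <- TRUE
    while (more) {
      c <- ((x %% 32) + 32) %% 32
      x <- (x - c) / 32            # arithmetic shift with floor semantics
      more <- if (c >= 16) x != -1 else x != 0
      if (more) c <- c + 32
      out <- c(out, c + 48)
    }
  }
  intToUtf8(out)
}

rect_mask <- function(h, w, y0, y1, x0, x1) {
  m <- matrix(0L, h, w)
  m[y0:y1, x0:x1] <- 1L
  m
}
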