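# Independent oracles (brute force / closed form) used to validate the
# package implementations, plus small shared fixtures.

# Per-pixel stroke rasterization: minimum distance from every pixel centre
# to every polyline segment, full-image double loop.
oracle_rasterize_lines <- function(polylines, H, W, thickness) {
  half <- thickness / 2
  mask <- matrix(0L, H, W)
  for (r in 0:(H - 1)) for (c in 0:(W - 1)) {
    hit <- FALSE
    for (poly in polylines) {
      n <- nrow(poly)
      segs <- if (n == 1) list(c(1, 1)) else
        lapply(seq_len(n - 1), function(i) c(i, i + 1))
      for (s in segs) {
        p <- poly[s[1], ]; q <- poly[s[2], ]
        v <- q - p; l2 <- sum(v^2)
        t <- if (l2 == 0) 0 else
          min(1, max(0, ((r - p[1]) * v[1] + (c - p[2]) * v[2]) / l2))
        d2 <- (r - (p[1] + t * v[1]))^2 + (c - (p[2] + t * v[2]))^2
        if (d2 <= half^2) { hit <- TRUE; break }
      }
      if (hit) break
    }
    if (hit) mask[r + 1, c + 1] <- 1L
  }
  mask
}

# Counting-loop IoU.
oracle_iou <- function(pred, target, cls) {
  inter <- 0L; uni <- 0L
  for (i in seq_along(pred)) {
    p <- pred[i] == cls; t <- target[i] == cls
    if (p && t) inter <- inter + 1L
    if (p || t) uni <- uni + 1L
  }
  if (uni == 0) 1.0 else inter / uni
}

# Exhaustive one-to-one assignment maximizing the true-positive count.
oracle_max_tp <- function(pred_pts, truth_pts, d_thresh) {
  np <- nrow(pred_pts); nt <- nrow(truth_pts)
  if (np == 0 || nt == 0) return(0L)
  d <- outer(seq_len(np), seq_len(nt), function(i, j)
    sqrt((pred_pts[i, 1] - truth_pts[j, 1])^2 +
         (pred_pts[i, 2] - truth_pts[j, 2])^2))
  best <- 0L
  recurse <- function(j, used_p, tp) {
    if (tp + (nt - j + 1) <= best) return()
    if (j > nt) { best <<- max(best, tp); return() }
    recurse(j + 1, used_p, tp)              # truth j unmatched
    for (i in seq_len(np)) {
      if (!used_p[i] && d[i, j] <= d_thresh) {
        used_p[i] <- TRUE
        recurse(j + 1, used_p, tp + 1L)
        used_p[i] <- FALSE
      }
    }
  }
  recurse(1L, logical(np), 0L)
  best
}

# Closed-form normal equations for col = a * row + b.
oracle_fit_line <- function(points) {
  y <- points[, 1]; x <- points[, 2]
  n <- length(y)
  a <- (n * sum(x * y) - sum(x) * sum(y)) / (n * sum(y^2) - sum(y)^2)
  b <- (sum(x) - a * sum(y)) / n
  list(a = a, b = b)
}

# Queue-based flood fill component count (8-connectivity).
oracle_component_count <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  seen <- matrix(FALSE, H, W)
  count <- 0L
  for (c0 in seq_len(W)) for (r0 in seq_len(H)) {
    if (mask[r0, c0] == 0 || seen[r0, c0]) next
    count <- count + 1L
    queue <- list(c(r0, c0)); seen[r0, c0] <- TRUE
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (dr in -1:1) for (dc in -1:1) {
        nr <- p[1] + dr; nc <- p[2] + dc
        if (nr >= 1 && nr <= H && nc >= 1 && nc <= W &&
            mask[nr, nc] != 0 && !seen[nr, nc]) {
          seen[nr, nc] <- TRUE
          queue[[length(queue) + 1]] <- c(nr, nc)
        }
      }
    }
  }
  count
}

# Explicit per-pixel weighted cross-entropy loop.
oracle_wce <- function(scores, target, weights) {
  d <- dim(scores)
  total <- 0
  for (n in seq_len(d[4])) for (h in seq_len(d[1])) for (w in seq_len(d[2])) {
    s <- scores[h, w, , n]
    p <- exp(s - max(s)); p <- p / sum(p)
    y <- target[h, w, n] + 1
    total <- total + weights[y] * log(p[y])
  }
  -total / (d[1] * d[2] * d[4])
}

# ---- fixtures --------------------------------------------------------------

# 96 x 96 paddy-line scene spec scaled for fast CPU training.
tiny_scene_spec <- function(seed = 11, weed_density = 0.5, ...) {
  scene_spec(image_height = 96, image_width = 96, n_rows = 4,
             row_spacing_at_bottom = 19, plant_spacing = 10,
             plant_radius_near = 4, plant_radius_far = 2,
             weed_density = weed_density, weed_radius_range = c(2, 3),
             jitter_sd = 1, seed = seed, ...)
}

tiny_line_dataset <- function(n = 8, seed = 11, thickness = 5) {
  seeds <- semgraphics:::sg_child_seeds(seed, n)
  lapply(seeds, function(s) {
    sp <- tiny_scene_spec(seed = s)
    sc <- generate_scene(sp)
    list(image = sc$image, mask = rasterize_lines(sc$truth, thickness),
         graphic = sc$truth, row_lines = sc$row_lines)
  })
}

# Tiny extended-skip config (the acceptance-scale network).
tiny_net_config <- function(...) {
  net_config(encoder_stages = list(c(2, 16), c(2, 32)), tail_blocks = 2,
             tail_kernel = 7, tail_separable = TRUE,
             skip_mode = "multiscale", multiscale_kernels = c(3, 5, 7),
             skip_branch_channels = 12, decoder_channels = 32,
             decoder_convs = 2, n_classes = 2, ...)
}

# Micro config for gradient checks and shape tests.
micro_net_config <- function(in_channels = 2, ...) {
  net_config(encoder_stages = list(c(1, 4), c(1, 6)), tail_blocks = 1,
             tail_kernel = 3, tail_separable = TRUE,
             skip_mode = "multiscale", multiscale_kernels = c(3),
             skip_branch_channels = 3, decoder_channels = 5,
             decoder_convs = 1, n_classes = 2, in_channels = in_channels, ...)
}

# Oracle "model" for evaluate_model(): returns stored ground-truth masks.
oracle_model <- function(masks, n_classes = 2) {
  structure(list(masks = masks, i = 0, config = list(n_classes = n_classes)),
            class = "oracle_model")
}
model_predict.oracle_model <- function(model, x) {
  # match by image dimensions is not possible; tests feed images in order
  env <- attr(model, "env")
  env$i <- env$i + 1
  model$masks[[env$i]]
}
make_oracle_model <- function(masks, n_classes = 2) {
  m <- oracle_model(masks, n_classes)
  attr(m, "env") <- new.env()
  attr(m, "env")$i <- 0
  registerS3method("model_predict", "oracle_model", model_predict.oracle_model,
                   envir = asNamespace("semgraphics"))
  m
}
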