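# Synthetic paddy-scene generator.
#
# Emulates near-field imagery of a row-transplanted paddy field shot from
# between the rows: straight crop rows anchored at the bottom edge converge
# toward a common vanishing point (perspective), plants are green blobs with
# leaf-like radial streaks whose radii shrink with depth, and grass weeds
# (wild millet) of overlapping colour sit in the inter-row gaps.  Every
# plant/weed base is recorded as an exact ground-truth keypoint and every
# row as a polyline, so downstream stages are testable without field data.

#' Specification of a synthetic paddy scene
#'
#' @param image_height,image_width image size in pixels (>= 64).
#' @param n_rows number of crop rows (>= 1).
#' @param vanishing_point `(row, col)` toward which rows converge; may lie
#'   above the image (negative row).
#' @param row_spacing_at_bottom spacing of row anchors on the bottom edge, px.
#' @param plant_spacing spacing of plants along a row, px.
#' @param plant_radius_near,plant_radius_far blob/annotation radii at the
#'   bottom of the image and at the far visible extent
#'   (`near >= far >= 1`: perspective).
#' @param weed_density expected weeds per inter-row gap (Poisson rate, >= 0).
#' @param weed_radius_range `(min, max)` weed radius, px.
#' @param jitter_sd positional noise of plant bases, px.
#' @param background_noise_sd pixel intensity noise of the soil/water
#'   background, on the `[0, 1]` scale.
#' @param horizon_frac top fraction of the image excluded from rows (only
#'   the near-field view is generated; default keeps the top 20 % empty).
#' @param seed integer seed; a fixed seed makes [generate_scene()]
#'   bit-reproducible.
#' @return an object of class `scene_spec`.
#' @export
scene_spec <- function(image_height = 512, image_width = 512, n_rows = 4,
                       vanishing_point = c(-0.5 * image_height, image_width / 2),
                       row_spacing_at_bottom = image_width / (n_rows + 1),
                       plant_spacing = 40,
                       plant_radius_near = 12, plant_radius_far = 4,
                       weed_density = 3, weed_radius_range = c(3, 8),
                       jitter_sd = 2, background_noise_sd = 0.02,
                       horizon_frac = 0.2, seed = 1) {
  spec <- list(image_height = as.integer(image_height),
               image_width = as.integer(image_width),
               n_rows = as.integer(n_rows),
               vanishing_point = as.numeric(vanishing_point),
               row_spacing_at_bottom = as.numeric(row_spacing_at_bottom),
               plant_spacing = as.numeric(plant_spacing),
               plant_radius_near = as.numeric(plant_radius_near),
               plant_radius_far = as.numeric(plant_radius_far),
               weed_density = as.numeric(weed_density),
               weed_radius_range = as.numeric(weed_radius_range),
               jitter_sd = as.numeric(jitter_sd),
               background_noise_sd = as.numeric(background_noise_sd),
               horizon_frac = as.numeric(horizon_frac),
               seed = as.integer(seed))
  validate_scene_spec(spec)
  structure(spec, class = "scene_spec")
}

validate_scene_spec <- function(s) {
  sg_check(s$image_height >= 64 && s$image_width >= 64,
           "image size must be at least 64 x 64")
  sg_check(s$n_rows >= 1, "n_rows must be >= 1")
  sg_check(s$row_spacing_at_bottom > 0, "row_spacing_at_bottom must be > 0")
  sg_check(s$plant_radius_near >= s$plant_radius_far && s$plant_radius_far >= 1,
           "need plant_radius_near >= plant_radius_far >= 1")
  sg_check(s$weed_density >= 0, "weed_density must be >= 0")
  sg_check(s$n_rows * s$row_spacing_at_bottom <= s$image_width,
           "n_rows * row_spacing_at_bottom (%.0f px) exceeds image_width (%d px)",
           s$n_rows * s$row_spacing_at_bottom, s$image_width)
  invisible(s)
}

# Analytic row geometry: col = a * row + b for each crop row, plus the
# visible vertical extent.  Rows are straight lines from evenly spaced
# bottom-edge anchors toward the common vanishing point.
scene_row_lines <- function(spec) {
  H <- spec$image_height; W <- spec$image_width
  vp <- spec$vanishing_point
  anchors <- (W - 1) / 2 +
    (seq_len(spec$n_rows) - (spec$n_rows + 1) / 2) * spec$row_spacing_at_bottom
  y_bottom <- H - 1
  a <- (anchors - vp[2]) / (y_bottom - vp[1])
  b <- vp[2] - a * vp[1]
  y_top <- ceiling(spec$horizon_frac * (H - 1))
  data.frame(a = a, b = b, y_min = y_top, y_max = y_bottom)
}

# Additive leaf-like blob: Gaussian radial falloff modulated by angular
# streaks, alpha-blended onto the image in place.
draw_blob <- function(img, r0, c0, radius, color, n_leaf, phase) {
  H <- dim(img)[1]; W <- dim(img)[2]
  ext <- ceiling(1.6 * radius)
  rmin <- max(0, floor(r0 - ext)); rmax <- min(H - 1, ceiling(r0 + ext))
  cmin <- max(0, floor(c0 - ext)); cmax <- min(W - 1, ceiling(c0 + ext))
  if (rmin > rmax || cmin > cmax) return(img)
  rr <- rep(rmin:rmax, times = cmax - cmin + 1)
  cc <- rep(cmin:cmax, each = rmax - rmin + 1)
  dr <- rr - r0; dc <- cc - c0
  d2 <- dr^2 + dc^2
  sigma <- radius / 1.4
  theta <- atan2(dc, dr)
  streak <- 0.55 + 0.45 * cos(n_leaf * theta + phase)^2
  alpha <- pmin(1, exp(-d2 / (2 * sigma^2)) * streak * 1.6)
  idx <- cbind(rr, cc) + 1L
  for (ch in 1:3) {
    ii <- cbind(idx, ch)
    img[ii] <- img[ii] * (1 - alpha) + color[ch] * alpha
  }
  img
}

#' Generate one synthetic paddy scene
#'
#' Deterministic for a fixed `spec$seed`.  Returns the rendered RGB image
#' together with exact ground truth: one polyline per crop row (points on
#' the analytic row line, ordered top to bottom), a paddy keypoint for
#' every plant base drawn, and a millet keypoint for every weed base.
#' Blob radii interpolate linearly from `plant_radius_near` at the image
#' bottom to `plant_radius_far` at the top of the visible row extent
#' (see [radius_from_depth()]).
#'
#' @param spec a [scene_spec()].
#' @return list with elements `image` (`(H, W, 3)` array in `[0, 1]`),
#'   `truth` (a [semantic_graphic()] carrying polylines and keypoints) and
#'   `row_lines` (data frame `a, b, y_min, y_max` of the analytic row
#'   geometry, `col = a * row + b`).
#' @export
generate_scene <- function(spec) {
  validate_scene_spec(spec)
  sg_with_seed(spec$seed, {
    H <- spec$image_height; W <- spec$image_width
    lines <- scene_row_lines(spec)
    y_top <- lines$y_min[1]; y_bottom <- lines$y_max[1]

    # muddy paddy-water background with pixel noise and a slight depth gradient
    base <- c(0.23, 0.21, 0.15)
    depth <- matrix(rep(seq(0.9, 1.05, length.out = H), W), H, W)
    img <- array(0, dim = c(H, W, 3))
    for (ch in 1:3)
      img[, , ch] <- base[ch] * depth +
        rnorm(H * W, 0, spec$background_noise_sd)

    paddy <- list(); millet <- list()

    for (i in seq_len(spec$n_rows)) {
      ys <- seq(y_bottom, y_top, by = -spec$plant_spacing)
      for (y0 in ys) {
        ry <- y0 + rnorm(1, 0, spec$jitter_sd)
        rx <- lines$a[i] * ry + lines$b[i] + rnorm(1, 0, spec$jitter_sd)
        ry <- min(max(ry, 0), H - 1); rx <- min(max(rx, 0), W - 1)
        rad <- radius_from_depth(ry, y_bottom, y_top,
                                 spec$plant_radius_near, spec$plant_radius_far)
        col <- pmin(pmax(c(0.20, 0.50, 0.16) + rnorm(3, 0, 0.04), 0), 1)
        img <- draw_blob(img, ry, rx, rad, col,
                         n_leaf = sample(3:5, 1), phase = runif(1, 0, pi))
        paddy[[length(paddy) + 1]] <- c(ry, rx, rad)
      }
    }

    if (spec$n_rows >= 2 && spec$weed_density > 0) {
      for (g in seq_len(spec$n_rows - 1)) {
        n_weed <- rpois(1, spec$weed_density)
        for (k in seq_len(n_weed)) {
          wy <- runif(1, y_top, y_bottom)
          x_lo <- lines$a[g] * wy + lines$b[g]
          x_hi <- lines$a[g + 1] * wy + lines$b[g + 1]
          margin <- 0.2 * (x_hi - x_lo)
          wx <- runif(1, x_lo + margin, x_hi - margin)
          wy <- min(max(wy, 0), H - 1); wx <- min(max(wx, 0), W - 1)
          wrad <- runif(1, spec$weed_radius_range[1], spec$weed_radius_range[2])
          col <- pmin(pmax(c(0.33, 0.47, 0.12) + rnorm(3, 0, 0.05), 0), 1)
          img <- draw_blob(img, wy, wx, wrad, col,
                           n_leaf = sample(4:6, 1), phase = runif(1, 0, pi))
          millet[[length(millet) + 1]] <- c(wy, wx, wrad)
        }
      }
    }

    img <- pmin(pmax(img, 0), 1)

    polys <- lapply(seq_len(spec$n_rows), function(i) {
      ys <- unique(c(seq(y_top, y_bottom, by = 8), y_bottom))
      xs <- pmin(pmax(lines$a[i] * ys + lines$b[i], 0), W - 1)
      cbind(ys, xs)
    })
    kp_df <- function(lst, cls) {
      if (!length(lst)) return(NULL)
      m <- do.call(rbind, lst)
      data.frame(class = cls, row = m[, 1], col = m[, 2], radius = m[, 3])
    }
    keypoints <- rbind(kp_df(paddy, "paddy"), kp_df(millet, "millet"))
    truth <- semantic_graphic(polylines = polys, keypoints = keypoints,
                              image_shape = c(H, W))
    list(image = img, truth = truth, row_lines = lines)
  })
}

#' Generate a dataset of synthetic scenes on disk
#'
#' Writes `n` scene PNGs plus annotation JSONs and a tab-separated manifest
#' of `image-path<TAB>annotation-path` pairs.  Per-sample seeds are derived
#' deterministically from `spec$seed` and the sample index, so the same
#' spec and `n` reproduce byte-identical annotations.
#'
#' @param spec a [scene_spec()].
#' @param n number of scenes (>= 1).
#' @param out_dir output directory (created if missing).
#' @return path of the manifest file, invisibly.
#' @export
generate_dataset <- function(spec, n, out_dir) {
  validate_scene_spec(spec)
  sg_check(n >= 1, "n must be >= 1")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sg_check(dir.exists(out_dir) && file.access(out_dir, 2) == 0,
           "output directory '%s' is not writable", out_dir)
  seeds <- sg_child_seeds(spec$seed, n)
  rows <- character(n)
  for (i in seq_len(n)) {
    spec_i <- spec; spec_i$seed <- seeds[i]
    scene <- generate_scene(spec_i)
    img_path <- file.path(out_dir, sprintf("scene_%04d.png", i))
    ann_path <- file.path(out_dir, sprintf("scene_%04d.json", i))
    write_png(scene$image, img_path)
    write_annotation(scene$truth, ann_path)
    rows[i] <- paste(basename(img_path), basename(ann_path), sep = "\t")
  }
  manifest <- file.path(out_dir, "manifest.tsv")
  writeLines(rows, manifest)
  invisible(manifest)
}

#' Read a dataset manifest
#'
#' @param manifest path to a TSV manifest written by [generate_dataset()].
#' @return data frame with absolute `image` and `annotation` paths.
#' @export
read_manifest <- function(manifest) {
  sg_check(file.exists(manifest), "manifest '%s' not found", manifest)
  m <- read.table(manifest, sep = "\t", stringsAsFactors = FALSE,
                  col.names = c("image", "annotation"))
  base <- dirname(manifest)
  m$image <- file.path(base, m$image)
  m$annotation <- file.path(base, m$annotation)
  m
}
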