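# Semantic-graphics data model and rasterization.
#
# Coordinate convention (package-wide): 0-based (row, col), origin at the
# top-left pixel centre, image bounds half-open [0, H) x [0, W).  Pixel
# (r, c) of a mask is the matrix entry [r + 1, c + 1].

#' Semantic-graphics annotation for one image
#'
#' A vector annotation holding crop-row polylines and/or class-labelled
#' keypoints with radii.  Polylines mark the (possibly occluded) straight
#' rows along which the crop was transplanted; keypoints mark plant bases,
#' with larger radii nearer the camera.
#'
#' @param polylines list of n x 2 matrices of `(row, col)` points (0-based).
#' @param keypoints data frame with columns `class` (character), `row`,
#'   `col`, `radius`, or `NULL` for a lines-only annotation.
#' @param image_shape integer `(height, width)`.
#' @param classes character vector of foreground class labels, in class-index
#'   order (index 1, 2, ... in rasterized masks; background is 0).
#' @return An object of class `semantic_graphic`.
#' @export
semantic_graphic <- function(polylines = list(), keypoints = NULL,
                             image_shape, classes = c("paddy", "millet")) {
  sg_check(length(image_shape) == 2 && all(image_shape >= 1),
           "image_shape must be (height, width)")
  H <- as.integer(image_shape[1]); W <- as.integer(image_shape[2])
  polylines <- lapply(polylines, function(p) {
    p <- matrix(as.numeric(p), ncol = 2)
    # clip into half-open bounds
    p[, 1] <- pmin(pmax(p[, 1], 0), H - 1)
    p[, 2] <- pmin(pmax(p[, 2], 0), W - 1)
    p
  })
  if (is.null(keypoints)) {
    keypoints <- data.frame(class = character(), row = numeric(),
                            col = numeric(), radius = numeric())
  } else {
    keypoints <- as.data.frame(keypoints)
    sg_check(all(c("class", "row", "col", "radius") %in% names(keypoints)),
             "keypoints need columns class, row, col, radius")
    bad <- setdiff(unique(keypoints$class), classes)
    if (length(bad))
      sg_stop("unknown keypoint class '%s' (declared: %s)", bad[1],
              paste(classes, collapse = ", "))
    sg_check(all(keypoints$radius > 0), "keypoint radius must be > 0")
    keypoints$row <- pmin(pmax(keypoints$row, 0), H - 1)
    keypoints$col <- pmin(pmax(keypoints$col, 0), W - 1)
  }
  structure(list(polylines = polylines, keypoints = keypoints,
                 image_shape = c(H, W), classes = classes),
            class = "semantic_graphic")
}

#' @export
print.semantic_graphic <- function(x, ...) {
  cat(sprintf("<semantic_graphic> %dx%d, %d polyline(s), %d keypoint(s) [%s]\n",
              x$image_shape[1], x$image_shape[2], length(x$polylines),
              nrow(x$keypoints), paste(x$classes, collapse = ", ")))
  invisible(x)
}

# Pixels (0-based) within `half` of the segment p--q, restricted to the
# image; returns an n x 2 matrix (row, col).
segment_stroke_pixels <- function(p, q, half, H, W) {
  rmin <- max(0, floor(min(p[1], q[1]) - half))
  rmax <- min(H - 1, ceiling(max(p[1], q[1]) + half))
  cmin <- max(0, floor(min(p[2], q[2]) - half))
  cmax <- min(W - 1, ceiling(max(p[2], q[2]) + half))
  if (rmin > rmax || cmin > cmax) return(NULL)
  rr <- rep(rmin:rmax, times = cmax - cmin + 1)
  cc <- rep(cmin:cmax, each = rmax - rmin + 1)
  v <- q - p
  l2 <- sum(v^2)
  if (l2 == 0) {
    d2 <- (rr - p[1])^2 + (cc - p[2])^2
  } else {
    t <- pmin(1, pmax(0, ((rr - p[1]) * v[1] + (cc - p[2]) * v[2]) / l2))
    d2 <- (rr - (p[1] + t * v[1]))^2 + (cc - (p[2] + t * v[2]))^2
  }
  keep <- d2 <= half^2
  if (!any(keep)) return(NULL)
  cbind(rr[keep], cc[keep])
}

#' Rasterize row polylines to a label mask
#'
#' Draws each polyline as a connected stroke of the given thickness
#' (class index 1 on background 0).  A pixel belongs to the stroke when
#' its centre lies within `thickness / 2` of any polyline segment
#' (round caps/joints); labelling is idempotent where strokes overlap.
#' A single-point polyline degenerates to a disc of diameter `thickness`.
#'
#' @param graphic a [semantic_graphic()].
#' @param thickness stroke thickness in pixels (odd, >= 1). The default
#'   5 px mirrors the few-pixel-thick strokes used for 600 x 600 imagery.
#' @return integer label mask matrix `(H, W)`, values 0/1.
#' @export
rasterize_lines <- function(graphic, thickness = 5) {
  sg_check(thickness >= 1 && is_odd(round(thickness)),
           "thickness must be an odd integer >= 1")
  H <- graphic$image_shape[1]; W <- graphic$image_shape[2]
  mask <- matrix(0L, H, W)
  half <- thickness / 2
  for (poly in graphic$polylines) {
    n <- nrow(poly)
    segs <- if (n == 1) list(list(poly[1, ], poly[1, ]))
            else lapply(seq_len(n - 1), function(i) list(poly[i, ], poly[i + 1, ]))
    for (s in segs) {
      px <- segment_stroke_pixels(s[[1]], s[[2]], half, H, W)
      if (!is.null(px)) mask[px + 1L] <- 1L
    }
  }
  mask
}

#' Rasterize keypoints to a label mask
#'
#' Each keypoint becomes a filled disc (Euclidean distance from centre
#' `<= radius`, ties included) carrying the class index of its label
#' (position in the graphic's `classes`, background = 0).  Keypoints are
#' drawn in list order; later discs overwrite earlier ones on overlap.
#'
#' @inheritParams rasterize_lines
#' @return integer label mask matrix `(H, W)`.
#' @export
rasterize_keypoints <- function(graphic) {
  H <- graphic$image_shape[1]; W <- graphic$image_shape[2]
  mask <- matrix(0L, H, W)
  kp <- graphic$keypoints
  for (i in seq_len(nrow(kp))) {
    cls <- match(kp$class[i], graphic$classes)
    px <- segment_stroke_pixels(c(kp$row[i], kp$col[i]),
                                c(kp$row[i], kp$col[i]),
                                kp$radius[i], H, W)
    if (!is.null(px)) mask[px + 1L] <- cls
  }
  mask
}

#' Depth-scaled annotation radius
#'
#' Linear interpolation of a disc radius with image row: plant bases near
#' the camera (bottom of the image, `y_near`) get radius `r_near`, bases
#' at the far end of the visible extent (`y_far`) get `r_far`; the result
#' is clamped to `[r_far, r_near]`.  When `y_near == y_far` (single depth)
#' the near radius is returned.
#'
#' @param y pixel row(s) at which to evaluate.
#' @param y_near,y_far rows of the near and far reference depths
#'   (`y_near > y_far`; the image bottom is near).
#' @param r_near,r_far radii at the reference depths (`r_near >= r_far > 0`).
#' @return radius in pixels (vectorized over `y`).
#' @export
radius_from_depth <- function(y, y_near, y_far, r_near, r_far) {
  sg_check(r_near >= r_far && r_far > 0, "need r_near >= r_far > 0")
  if (y_near == y_far) return(rep(r_near, length(y)))
  sg_check(y_near > y_far, "need y_near > y_far (image bottom is near)")
  t <- (y - y_far) / (y_near - y_far)
  pmin(pmax(r_far + t * (r_near - r_far), r_far), r_near)
}

#' Inverse-frequency class weights
#'
#' Computes per-class loss weights from a set of label masks:
#' `w_c = total_pixels / (L * pixels_of_class_c)` with `L` the number of
#' classes including background.  A uniform class distribution yields
#' all-ones, and `sum_c w_c * freq_c = 1`.  Used to counter the extreme
#' background/foreground imbalance of rasterized graphics.
#'
#' @param masks a label mask matrix or list of them.
#' @param n_classes number of classes including background; defaults to
#'   `max(mask) + 1`.
#' @param class_names optional labels used in error messages and names.
#' @return numeric vector of `L` positive weights (background first).
#' @export
compute_class_weights <- function(masks, n_classes = NULL, class_names = NULL) {
  if (is.matrix(masks)) masks <- list(masks)
  sg_check(length(masks) >= 1, "need at least one mask")
  L <- n_classes %||% (max(vapply(masks, max, 0)) + 1L)
  counts <- Reduce(`+`, lapply(masks, function(m) tabulate(m + 1L, nbins = L)))
  names(counts) <- class_names %||% as.character(seq_len(L) - 1L)
  if (any(counts == 0))
    sg_stop("class '%s' absent from all masks; weights undefined",
            names(counts)[which(counts == 0)[1]])
  w <- sum(counts) / (L * counts)
  names(w) <- names(counts)
  w
}

#' Read and write annotation JSON
#'
#' Serialization of a [semantic_graphic()] with top-level keys
#' `"polylines"` (list of `[row, col]` point lists), `"keypoints"`
#' (list of `{"class", "center": [row, col], "radius"}`) and
#' `"image_shape"`.  A file without a `"keypoints"` key yields an empty
#' keypoint table (lines-only datasets); schema violations (unknown class,
#' non-positive radius) are rejected with the offending field named.
#'
#' @param graphic a [semantic_graphic()].
#' @param path JSON file path.
#' @param classes declared class set used to validate keypoint labels.
#' @return `read_annotation()`: a [semantic_graphic()];
#'   `write_annotation()`: `path`, invisibly.
#' @export
write_annotation <- function(graphic, path) {
  obj <- list(
    image_shape = as.integer(graphic$image_shape),
    classes = as.list(graphic$classes),
    polylines = lapply(graphic$polylines, function(p)
      lapply(seq_len(nrow(p)), function(i) as.numeric(p[i, ]))),
    keypoints = lapply(seq_len(nrow(graphic$keypoints)), function(i)
      list(class = graphic$keypoints$class[i],
           center = c(graphic$keypoints$row[i], graphic$keypoints$col[i]),
           radius = graphic$keypoints$radius[i]))
  )
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = I(8))
  writeLines(json, path)
  invisible(path)
}

#' @rdname write_annotation
#' @export
read_annotation <- function(path, classes = c("paddy", "millet")) {
  obj <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e) sg_stop("malformed annotation JSON '%s': %s",
                                              path, conditionMessage(e)))
  sg_check(!is.null(obj$image_shape), "annotation '%s': missing field 'image_shape'", path)
  if (!is.null(obj$classes)) classes <- unlist(obj$classes)
  polylines <- lapply(obj$polylines %||% list(), function(pl) {
    do.call(rbind, lapply(pl, function(pt) {
      sg_check(length(pt) == 2, "annotation '%s': polyline point is not [row, col]", path)
      as.numeric(pt)
    }))
  })
  kps <- obj$keypoints %||% list()
  keypoints <- if (length(kps) == 0) NULL else {
    df <- do.call(rbind, lapply(kps, function(k) {
      sg_check(!is.null(k$class) && !is.null(k$center) && !is.null(k$radius),
               "annotation '%s': keypoint missing class/center/radius", path)
      sg_check(k$radius > 0, "annotation '%s': field 'radius' must be > 0", path)
      data.frame(class = as.character(k$class),
                 row = as.numeric(k$center[[1]]), col = as.numeric(k$center[[2]]),
                 radius = as.numeric(k$radius))
    }))
    df
  }
  semantic_graphic(polylines = polylines, keypoints = keypoints,
                   image_shape = unlist(obj$image_shape), classes = classes)
}
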