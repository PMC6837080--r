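# Dominant semantic-line extraction (simplified RANSAC).
#
# Crop rows are near-vertical, so lines are parameterized as
# col = a * row + b (x as a function of y), which keeps vertical rows
# finite, and the inlier distance is horizontal |col - (a*row + b)| --
# the same axis the mean-pixel-deviation metric is defined on.

#' Binarize class scores to a foreground mask
#'
#' A pixel is foreground iff the argmax over classes equals `class_index`
#' (invariant under softmax or any monotone per-pixel rescaling).
#'
#' @param scores `(H, W, L)` or `(H, W, L, 1)` class scores.
#' @param class_index 0-based class index (default 1 = the line class).
#' @return integer 0/1 matrix `(H, W)`.
#' @export
binarize_scores <- function(scores, class_index = 1) {
  if (length(dim(scores)) == 3) dim(scores) <- c(dim(scores), 1L)
  sg_check(class_index >= 0 && class_index < dim(scores)[3],
           "class_index out of range")
  mask <- scores_to_mask(scores)
  matrix(as.integer(mask == class_index), nrow(mask), ncol(mask))
}

#' Connected components of a binary mask, sorted by size
#'
#' 8-connected components; "length" of a segment is its pixel count.
#' Components are returned in descending size order, ties broken by the
#' topmost (then leftmost) pixel for determinism.
#'
#' @param mask integer 0/1 matrix.
#' @return list of components, each `list(pixels, size)` with `pixels` an
#'   n x 2 matrix of 0-based `(row, col)` coordinates.
#' @export
segment_components <- function(mask) {
  sg_check(is.matrix(mask), "mask must be a matrix")
  lab <- cpp_label_components(matrix(as.integer(mask != 0), nrow(mask)), 8L)
  k <- max(lab)
  if (k == 0) return(list())
  comps <- lapply(seq_len(k), function(i) {
    px <- which(lab == i, arr.ind = TRUE) - 1L
    colnames(px) <- c("row", "col")
    list(pixels = px, size = nrow(px))
  })
  sizes <- vapply(comps, `[[`, 0, "size")
  top <- vapply(comps, function(co) min(co$pixels[, 1]), 0)
  left <- vapply(comps, function(co) {
    r0 <- min(co$pixels[, 1])
    min(co$pixels[co$pixels[, 1] == r0, 2])
  }, 0)
  comps[order(-sizes, top, left)]
}

#' Least-squares line fit, col = a * row + b
#'
#' @param points n x 2 matrix of 0-based `(row, col)` points with at least
#'   two distinct rows.
#' @return list `(a, b)`.
#' @export
fit_line <- function(points) {
  points <- matrix(as.numeric(points), ncol = 2)
  sg_check(nrow(points) >= 2, "need at least 2 points")
  sg_check(length(unique(points[, 1])) >= 2,
           "all points in one image row; col = a*row + b is undefined")
  fit <- stats::.lm.fit(cbind(1, points[, 1]), points[, 2])
  list(a = unname(fit$coefficients[2]), b = unname(fit$coefficients[1]))
}

line_inliers <- function(points, a, b, d_thresh) {
  abs(points[, 2] - (a * points[, 1] + b)) <= d_thresh
}

#' Extract dominant crop lines from a binary mask
#'
#' Simplified RANSAC over connected line segments: (1) the longest
#' remaining segment seeds a least-squares line; (2) all remaining
#' foreground pixels within `d_thresh` horizontally are taken as inliers
#' and the line is refit; (3) the refit line's inliers are collected once
#' more and the second iteration's line is final.  The line's inliers and
#' every segment with more than `overlap_frac` of its pixels among them
#' are then excluded, and the procedure repeats until `n_lines` lines are
#' found or no admissible seed remains.  Inlier sets of distinct lines
#' are disjoint by construction.
#'
#' @param mask integer 0/1 matrix.
#' @param n_lines number of dominant lines requested (the field default
#'   is 4: the host row and its neighbours).
#' @param d_thresh horizontal inlier distance, px (published value 15).
#' @param overlap_frac segment-exclusion threshold (published value 0.5).
#' @param min_seed minimum pixels for a segment to seed a line (guards
#'   against speckle; not part of the published procedure).
#' @return object of class `dominant_lines`: list with `lines` (each
#'   `list(a, b, inliers, y_min, y_max, n_inliers)`) and `shortfall`
#'   (`n_lines - length(lines)`).
#' @export
extract_dominant_lines <- function(mask, n_lines = 4, d_thresh = 15,
                                   overlap_frac = 0.5, min_seed = 20) {
  sg_check(n_lines >= 1, "n_lines must be >= 1")
  n_lines <- as.integer(n_lines)
  comps <- segment_components(mask)
  active <- rep(TRUE, length(comps))
  assigned <- matrix(FALSE, nrow(mask), ncol(mask))
  lines <- list()

  seed_ok <- function(co) {
    co$size >= min_seed && length(unique(co$pixels[, 1])) >= 2
  }

  while (length(lines) < n_lines) {
    si <- which(active & vapply(comps, seed_ok, TRUE))[1]
    if (is.na(si)) break
    seed <- comps[[si]]
    l0 <- fit_line(seed$pixels)

    fg <- which(mask != 0 & !assigned, arr.ind = TRUE) - 1L
    if (nrow(fg) < 2) break
    # iteration 1: inliers of the seed line, refit; iteration 2: inliers
    # of the refit line -- that refit is the dominant line.
    pts <- fg[line_inliers(fg, l0$a, l0$b, d_thresh), , drop = FALSE]
    if (nrow(pts) >= 2 && length(unique(pts[, 1])) >= 2) l0 <- fit_line(pts)
    inl <- fg[line_inliers(fg, l0$a, l0$b, d_thresh), , drop = FALSE]

    assigned[inl + 1L] <- TRUE
    active[si] <- FALSE
    for (ci in which(active)) {
      px <- comps[[ci]]$pixels
      frac <- mean(assigned[px + 1L])
      if (frac > overlap_frac) active[ci] <- FALSE
    }
    lines[[length(lines) + 1]] <- list(a = l0$a, b = l0$b, inliers = inl,
                                       y_min = min(inl[, 1]),
                                       y_max = max(inl[, 1]),
                                       n_inliers = nrow(inl))
  }
  structure(list(lines = lines, shortfall = n_lines - length(lines)),
            class = "dominant_lines")
}

#' @export
print.dominant_lines <- function(x, ...) {
  cat(sprintf("<dominant_lines> %d line(s)%s\n", length(x$lines),
              if (x$shortfall > 0) sprintf(" (shortfall %d)", x$shortfall) else ""))
  for (l in x$lines)
    cat(sprintf("  col = %+.4f * row + %8.3f   rows [%d, %d], %d inliers\n",
                l$a, l$b, l$y_min, l$y_max, l$n_inliers))
  invisible(x)
}

#' Serialize extracted lines to JSON
#'
#' @param result a `dominant_lines` object.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_lines_json <- function(result, path) {
  obj <- lapply(result$lines, function(l)
    list(a = l$a, b = l$b, y_min = l$y_min, y_max = l$y_max,
         n_inliers = l$n_inliers))
  writeLines(jsonlite::toJSON(list(lines = obj, shortfall = result$shortfall),
                              auto_unbox = TRUE, digits = I(8)), path)
  invisible(path)
}
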