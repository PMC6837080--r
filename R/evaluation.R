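# Evaluation metrics: per-class IoU / mIoU, distance-thresholded keypoint
# precision/recall/F1, and mean pixel deviation of extracted lines.

#' Intersection-over-union for one class
#'
#' `|T intersect P| / |T union P|` over the class's pixel sets; defined as
#' 1.0 when both sets are empty (a correctly predicted absent class).
#' Symmetric in its arguments.
#'
#' @param pred,target integer label masks of equal shape.
#' @param class_index 0-based class index.
#' @return fraction in `[0, 1]`.
#' @export
iou <- function(pred, target, class_index) {
  sg_check(all(dim(pred) == dim(target)), "pred and target shapes differ")
  p <- pred == class_index
  t <- target == class_index
  u <- sum(p | t)
  if (u == 0) return(1.0)
  sum(p & t) / u
}

# centroids of connected components of one class -> n x 2 (row, col), 0-based
class_centroids <- function(mask, class_index) {
  lab <- cpp_label_components(matrix(as.integer(mask == class_index),
                                     nrow(mask)), 8L)
  k <- max(lab)
  if (k == 0) return(matrix(numeric(), 0, 2))
  t(vapply(seq_len(k), function(i) {
    px <- which(lab == i, arr.ind = TRUE) - 1L
    c(mean(px[, 1]), mean(px[, 2]))
  }, numeric(2)))
}

# Greedy one-to-one matching in ascending distance order; returns TP count.
greedy_match_count <- function(pred_pts, truth_pts, d_thresh) {
  np <- nrow(pred_pts); nt <- nrow(truth_pts)
  if (np == 0 || nt == 0) return(0L)
  d <- outer(seq_len(np), seq_len(nt), function(i, j)
    sqrt((pred_pts[i, 1] - truth_pts[j, 1])^2 +
         (pred_pts[i, 2] - truth_pts[j, 2])^2))
  ord <- order(d)
  used_p <- logical(np); used_t <- logical(nt)
  tp <- 0L
  for (o in ord) {
    if (d[o] > d_thresh) break
    i <- (o - 1) %% np + 1; j <- (o - 1) %/% np + 1
    if (used_p[i] || used_t[j]) next
    used_p[i] <- TRUE; used_t[j] <- TRUE
    tp <- tp + 1L
  }
  tp
}

prf_from_counts <- function(tp, fp, fn) {
  precision <- if (tp + fp == 0) 1.0 else tp / (tp + fp)
  recall <- if (tp + fn == 0) 1.0 else tp / (tp + fn)
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  c(precision = precision, recall = recall, f1 = f1)
}

#' Keypoint detection precision/recall/F1 at a distance threshold
#'
#' Predicted keypoint centres are the centroids of the 8-connected
#' components of each class in the predicted mask.  Predictions and
#' ground-truth centres are matched one-to-one greedily in ascending
#' distance order; a match within `d_thresh` pixels is a true positive,
#' unmatched predictions are false positives and unmatched truths false
#' negatives.  When a class has neither predictions nor truths,
#' precision and recall are 1 by convention.
#'
#' @param pred integer label mask.
#' @param truth data frame with columns `class`, `row`, `col` (keypoint
#'   centres).
#' @param d_thresh matching distance threshold, px (published value 15).
#' @param classes foreground class labels in class-index order.
#' @return data frame, one row per class: tp, fp, fn, precision, recall, f1.
#' @export
keypoint_prf <- function(pred, truth, d_thresh = 15,
                         classes = c("paddy", "millet")) {
  sg_check(d_thresh > 0, "d_thresh must be > 0")
  out <- lapply(seq_along(classes), function(ci) {
    cents <- class_centroids(pred, ci)
    tr <- truth[truth$class == classes[ci], c("row", "col"), drop = FALSE]
    tr <- as.matrix(tr)
    tp <- greedy_match_count(cents, tr, d_thresh)
    fp <- nrow(cents) - tp
    fn <- nrow(tr) - tp
    c(tp = tp, fp = fp, fn = fn, prf_from_counts(tp, fp, fn))
  })
  df <- as.data.frame(do.call(rbind, out))
  df <- cbind(class = classes, df)
  rownames(df) <- NULL
  df
}

# Mean |x_p - x_g| between two lines over the integer rows shared by their
# y-extents; Inf when the extents are disjoint.
line_pair_rows <- function(pl, gl) {
  ys <- seq(max(pl$y_min, gl$y_min), min(pl$y_max, gl$y_max))
  if (length(ys) == 0 || ys[1] > ys[length(ys)]) return(NULL)
  ys
}

#' Mean pixel deviation between predicted and ground-truth lines
#'
#' Predicted lines are matched one-to-one to ground-truth lines greedily
#' by minimal mean horizontal deviation over shared rows.  For each
#' matched pair, the row-wise pixel deviation is `pd = |x_p - x_g|`
#' evaluated on every integer row in the intersection of the two
#' y-extents; `mpd` pools the rows of all matched lines, and
#' `deviation_range` is the `(min, max)` of the signed deviation
#' `x_p - x_g`.  Unmatched ground-truth lines are tallied as `missed`
#' (they do not contribute rows); with no predicted lines at all,
#' `mpd` is `NaN`.
#'
#' @param pred_lines list of lines `list(a, b, y_min, y_max)` (e.g. from
#'   [extract_dominant_lines()]`$lines`).
#' @param gt_lines list or data frame of ground-truth lines with fields
#'   `a, b, y_min, y_max`.
#' @param y_range optional `(y_min, y_max)` restriction applied to all
#'   lines before matching.
#' @return list `(mpd, deviation_range, missed, n_matched, n_rows)`.
#' @export
mean_pixel_deviation <- function(pred_lines, gt_lines, y_range = NULL) {
  if (is.data.frame(gt_lines))
    gt_lines <- lapply(seq_len(nrow(gt_lines)), function(i) as.list(gt_lines[i, ]))
  if (inherits(pred_lines, "dominant_lines")) pred_lines <- pred_lines$lines
  sg_check(length(gt_lines) >= 1, "need at least one ground-truth line")
  clipln <- function(l) {
    if (!is.null(y_range)) {
      l$y_min <- max(l$y_min, y_range[1]); l$y_max <- min(l$y_max, y_range[2])
    }
    l
  }
  pred_lines <- lapply(pred_lines, clipln)
  gt_lines <- lapply(gt_lines, clipln)
  np <- length(pred_lines); ng <- length(gt_lines)
  if (np == 0)
    return(list(mpd = NaN, deviation_range = c(NA, NA), missed = ng,
                n_matched = 0L, n_rows = 0L))

  cost <- matrix(Inf, np, ng)
  for (i in seq_len(np)) for (j in seq_len(ng)) {
    ys <- line_pair_rows(pred_lines[[i]], gt_lines[[j]])
    if (!is.null(ys)) {
      xp <- pred_lines[[i]]$a * ys + pred_lines[[i]]$b
      xg <- gt_lines[[j]]$a * ys + gt_lines[[j]]$b
      cost[i, j] <- mean(abs(xp - xg))
    }
  }
  used_p <- logical(np); used_g <- logical(ng)
  devs <- numeric(0)
  n_matched <- 0L
  for (o in order(cost)) {
    if (!is.finite(cost[o])) break
    i <- (o - 1) %% np + 1; j <- (o - 1) %/% np + 1
    if (used_p[i] || used_g[j]) next
    used_p[i] <- TRUE; used_g[j] <- TRUE
    n_matched <- n_matched + 1L
    ys <- line_pair_rows(pred_lines[[i]], gt_lines[[j]])
    devs <- c(devs, (pred_lines[[i]]$a * ys + pred_lines[[i]]$b) -
                    (gt_lines[[j]]$a * ys + gt_lines[[j]]$b))
  }
  list(mpd = if (length(devs)) mean(abs(devs)) else NaN,
       deviation_range = if (length(devs)) c(min(devs), max(devs)) else c(NA, NA),
       missed = ng - n_matched, n_matched = n_matched,
       n_rows = length(devs))
}

#' Evaluate a model on a dataset
#'
#' Runs forward passes in evaluation mode, converts scores to label masks
#' by argmax, and computes the metrics applicable to the task.  IoU is
#' aggregated at the dataset level by pooling intersection and union
#' counts across images (robust to images where a class is absent);
#' per-image averaging is available via `per_image = TRUE`.  `miou`
#' averages all classes including background; `miou_foreground` averages
#' foreground classes only (the convention used for two-foreground-class
#' keypoint reports).  For the line task, dominant lines are extracted
#' from each predicted mask and compared against least-squares fits of
#' the ground-truth polylines via [mean_pixel_deviation()].
#'
#' @param model an `sg_model`.
#' @param dataset list of `list(image, mask, graphic)` (see [load_dataset()]).
#' @param task `"lines"` or `"keypoints"`.
#' @param d_thresh keypoint-matching / line-inlier threshold, px.
#' @param n_lines dominant lines to extract per image (line task).
#' @param extract_lines run the dominant-line post-processing (line task).
#' @param per_image additionally report the mean of per-image IoUs.
#' @param classes foreground class labels for the keypoint task.
#' @return object of class `eval_report` (a list; see fields in details).
#' @export
evaluate_model <- function(model, dataset, task = c("lines", "keypoints"),
                           d_thresh = 15, n_lines = 4, extract_lines = TRUE,
                           per_image = FALSE,
                           classes = c("paddy", "millet")) {
  task <- match.arg(task)
  L <- model$config$n_classes
  inter <- numeric(L); uni <- numeric(L)
  per_image_iou <- matrix(NA_real_, length(dataset), L)
  kp_counts <- NULL
  all_devs <- numeric(0)
  missed <- 0L; total_gt_lines <- 0L

  for (i in seq_along(dataset)) {
    d <- dataset[[i]]
    pred <- model_predict(model, d$image)
    for (c in seq_len(L) - 1L) {
      p <- pred == c; t <- d$mask == c
      inter[c + 1] <- inter[c + 1] + sum(p & t)
      uni[c + 1] <- uni[c + 1] + sum(p | t)
      per_image_iou[i, c + 1] <- iou(pred, d$mask, c)
    }
    if (task == "keypoints") {
      prf <- keypoint_prf(pred, d$graphic$keypoints, d_thresh, classes)
      cnt <- as.matrix(prf[, c("tp", "fp", "fn")])
      kp_counts <- if (is.null(kp_counts)) cnt else kp_counts + cnt
    } else if (extract_lines) {
      gt_lines <- lapply(d$graphic$polylines, function(p) {
        fl <- fit_line(p)
        list(a = fl$a, b = fl$b, y_min = min(p[, 1]), y_max = max(p[, 1]))
      })
      total_gt_lines <- total_gt_lines + length(gt_lines)
      ex <- extract_dominant_lines(matrix(as.integer(pred == 1), nrow(pred)),
                                   n_lines = min(n_lines, length(gt_lines)),
                                   d_thresh = d_thresh)
      mp <- mean_pixel_deviation(ex$lines, gt_lines)
      missed <- missed + mp$missed
      all_devs <- c(all_devs, pooled_devs(ex$lines, gt_lines))
    }
  }

  class_iou <- ifelse(uni == 0, 1, inter / uni)
  names(class_iou) <- if (L == 2) c("background", "line")
                      else c("background", classes)[seq_len(L)]
  report <- list(task = task, n_images = length(dataset),
                 per_class_iou = as.list(class_iou),
                 miou = mean(class_iou),
                 miou_foreground = mean(class_iou[-1]))
  if (per_image)
    report$miou_per_image <- mean(rowMeans(per_image_iou))
  if (task == "keypoints") {
    prf <- t(apply(kp_counts, 1, function(r)
      prf_from_counts(r["tp"], r["fp"], r["fn"])))
    report$keypoints <- cbind(data.frame(class = classes),
                              as.data.frame(kp_counts),
                              as.data.frame(prf))
  } else if (extract_lines) {
    report$mpd <- if (length(all_devs)) mean(abs(all_devs)) else NaN
    report$deviation_range <- if (length(all_devs))
      c(min(all_devs), max(all_devs)) else c(NA, NA)
    report$missed_lines <- missed
    report$total_gt_lines <- total_gt_lines
  }
  structure(report, class = "eval_report")
}

# signed deviations of greedily matched line pairs, pooled over rows
pooled_devs <- function(pred_lines, gt_lines) {
  np <- length(pred_lines); ng <- length(gt_lines)
  if (np == 0 || ng == 0) return(numeric(0))
  cost <- matrix(Inf, np, ng)
  for (i in seq_len(np)) for (j in seq_len(ng)) {
    ys <- line_pair_rows(pred_lines[[i]], gt_lines[[j]])
    if (!is.null(ys))
      cost[i, j] <- mean(abs((pred_lines[[i]]$a * ys + pred_lines[[i]]$b) -
                             (gt_lines[[j]]$a * ys + gt_lines[[j]]$b)))
  }
  used_p <- logical(np); used_g <- logical(ng)
  devs <- numeric(0)
  for (o in order(cost)) {
    if (!is.finite(cost[o])) break
    i <- (o - 1) %% np + 1; j <- (o - 1) %/% np + 1
    if (used_p[i] || used_g[j]) next
    used_p[i] <- TRUE; used_g[j] <- TRUE
    ys <- line_pair_rows(pred_lines[[i]], gt_lines[[j]])
    devs <- c(devs, (pred_lines[[i]]$a * ys + pred_lines[[i]]$b) -
                    (gt_lines[[j]]$a * ys + gt_lines[[j]]$b))
  }
  devs
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> task '%s', %d image(s)\n", x$task, x$n_images))
  for (nm in names(x$per_class_iou))
    cat(sprintf("  IoU[%s] = %.4f\n", nm, x$per_class_iou[[nm]]))
  cat(sprintf("  mIoU = %.4f (foreground-only %.4f)\n", x$miou,
              x$miou_foreground))
  if (!is.null(x$mpd))
    cat(sprintf("  mpd = %.3f px, deviation range [%.1f, %.1f], missed %d/%d\n",
                x$mpd, x$deviation_range[1], x$deviation_range[2],
                x$missed_lines, x$total_gt_lines))
  if (!is.null(x$keypoints)) print(x$keypoints)
  invisible(x)
}

#' Write and read evaluation reports as JSON
#'
#' @param report an `eval_report`.
#' @param path JSON file path.
#' @return `read_report()` returns the report list.
#' @export
write_report <- function(report, path) {
  writeLines(jsonlite::toJSON(unclass(report), auto_unbox = TRUE,
                              digits = I(10), dataframe = "rows",
                              na = "null"), path)
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  jsonlite::fromJSON(path, simplifyVector = TRUE)
}
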