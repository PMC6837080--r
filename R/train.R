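# Training loop: Adam, stepwise exponential learning-rate decay, seeded
# shuffling and augmentation, per-epoch history with train mIoU.

#' Training configuration
#'
#' Published settings: the line task used mini-batches of 5 with Adam, an
#' exponentially decaying learning rate starting at `1e-4`, 100 epochs;
#' the keypoint task used mini-batches of 10, base rate `1e-4` decayed by
#' a factor 0.94 after every 10,000 iterations, 60,000 iterations total.
#' The decay here is stepwise: `lr = base_lr * factor^floor(step/interval)`.
#'
#' @param batch_size mini-batch size (>= 1).
#' @param base_lr initial learning rate (> 0).
#' @param lr_decay_factor multiplicative decay per interval (0 < f <= 1).
#' @param lr_decay_interval steps between decays.
#' @param total_epochs passes over the training set.
#' @param seed integer seed governing initialization order, shuffling and
#'   augmentation.
#' @param augmentation an [aug_spec()] or `NULL` to train on raw pairs.
#' @param class_weights `"auto"` (inverse-frequency from the training
#'   masks), a numeric vector, or `NULL` for unit weights.
#' @param stop_miou optional early-stop threshold on train mIoU.
#' @param checkpoint_path optional path; the best-mIoU model is saved there.
#' @param verbose print a line per epoch.
#' @return an object of class `train_config`.
#' @export
train_config <- function(batch_size = 5, base_lr = 1e-4,
                         lr_decay_factor = 0.94, lr_decay_interval = 10000,
                         total_epochs = 100, seed = 1, augmentation = NULL,
                         class_weights = "auto", stop_miou = NULL,
                         checkpoint_path = NULL, verbose = FALSE) {
  sg_check(batch_size >= 1, "batch_size must be >= 1")
  sg_check(base_lr > 0, "base_lr must be > 0")
  sg_check(lr_decay_factor > 0 && lr_decay_factor <= 1,
           "lr_decay_factor must be in (0, 1]")
  sg_check(lr_decay_interval >= 1, "lr_decay_interval must be >= 1")
  structure(list(batch_size = as.integer(batch_size), base_lr = base_lr,
                 lr_decay_factor = lr_decay_factor,
                 lr_decay_interval = as.integer(lr_decay_interval),
                 total_epochs = as.integer(total_epochs),
                 seed = as.integer(seed), augmentation = augmentation,
                 class_weights = class_weights, stop_miou = stop_miou,
                 checkpoint_path = checkpoint_path,
                 verbose = isTRUE(verbose)),
            class = "train_config")
}

#' Stepwise exponential learning-rate schedule
#'
#' `rate = base_lr * decay_factor^floor(step / decay_interval)`.  With the
#' published keypoint-task settings (base `1e-4`, factor 0.94, interval
#' 10,000) this gives `1e-4` at step 0 and `9.4e-5` at step 10,000.
#' Non-increasing in `step` whenever `decay_factor <= 1`.
#'
#' @param step 0-based optimizer step (vectorized).
#' @param config a [train_config()]; alternatively pass the three rate
#'   parameters directly.
#' @param base_lr,decay_factor,decay_interval used when `config` is missing.
#' @return learning rate(s).
#' @export
lr_schedule <- function(step, config = NULL, base_lr = 1e-4,
                        decay_factor = 0.94, decay_interval = 10000) {
  if (!is.null(config)) {
    base_lr <- config$base_lr
    decay_factor <- config$lr_decay_factor
    decay_interval <- config$lr_decay_interval
  }
  sg_check(all(step >= 0), "step must be >= 0")
  base_lr * decay_factor^floor(step / decay_interval)
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (key in names(grads)) {
    g <- grads[[key]]
    state$m[[key]] <- beta1 * state$m[[key]] + (1 - beta1) * g
    state$v[[key]] <- beta2 * state$v[[key]] + (1 - beta2) * g * g
    params[[key]] <- params[[key]] -
      lr * (state$m[[key]] / bc1) / (sqrt(state$v[[key]] / bc2) + eps)
  }
  list(params = params, state = state)
}

# Pooled-count mIoU between an argmax prediction and a target batch,
# used for the in-training history (all classes, including background).
batch_iou_counts <- function(pred, target, L) {
  inter <- integer(L); uni <- integer(L)
  for (c in seq_len(L) - 1L) {
    p <- pred == c; t <- target == c
    inter[c + 1] <- sum(p & t)
    uni[c + 1] <- sum(p | t)
  }
  cbind(inter = inter, union = uni)
}

counts_to_miou <- function(counts) {
  iou <- ifelse(counts[, "union"] == 0, 1, counts[, "inter"] / counts[, "union"])
  mean(iou)
}

#' Train a model
#'
#' Runs mini-batch Adam on the class-weighted pixel-wise cross-entropy.
#' Weights are Xavier-initialized at [build_model()] time; the training
#' loop seeds everything else (per-epoch shuffling, augmentation draws).
#' Per-epoch history records the loss, learning rate and train mIoU
#' computed from the training batches' own argmax predictions; the
#' best-mIoU weights are kept (and written to `config$checkpoint_path`
#' when set).  Training aborts with a diagnostic if the loss becomes
#' non-finite.
#'
#' @param model an `sg_model` from [build_model()].
#' @param dataset list of `list(image, mask)` pairs (see [load_dataset()]).
#' @param config a [train_config()].
#' @return list with `model` (best-mIoU weights), `final_model`,
#'   `history` (data frame: epoch, step, lr, loss, miou), `best_miou`,
#'   and the `class_weights` used.
#' @export
train_model <- function(model, dataset, config) {
  sg_check(length(dataset) >= 1, "dataset is empty")
  L <- model$config$n_classes

  cw <- config$class_weights
  if (identical(cw, "auto")) {
    cw <- compute_class_weights(lapply(dataset, `[[`, "mask"), n_classes = L)
  } else if (is.null(cw)) {
    cw <- rep(1, L)
  }
  sg_check(length(cw) == L, "class_weights must have one entry per class")

  params <- model_params(model)
  state <- adam_init(params)
  step <- 0L
  history <- list()
  best <- list(miou = -Inf, params = params)

  epoch_seeds <- sg_child_seeds(config$seed, config$total_epochs)
  for (epoch in seq_len(config$total_epochs)) {
    res <- sg_with_seed(epoch_seeds[epoch], {
      ord <- sample(length(dataset))
      ep_loss <- 0; n_batches <- 0L
      counts <- NULL
      batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
      for (bi in batches) {
        pairs <- lapply(dataset[bi], function(d) {
          if (!is.null(config$augmentation))
            augment_pair(d$image, d$mask, config$augmentation)[c("image", "mask")]
          else d[c("image", "mask")]
        })
        hb <- dim(pairs[[1]]$image)[1]; wb <- dim(pairs[[1]]$image)[2]
        x <- array(0, dim = c(hb, wb, dim(pairs[[1]]$image)[3], length(pairs)))
        y <- array(0L, dim = c(hb, wb, length(pairs)))
        for (k in seq_along(pairs)) {
          x[, , , k] <- pairs[[k]]$image
          y[, , k] <- pairs[[k]]$mask
        }
        fw <- model_forward(model, x, training = TRUE, keep_cache = TRUE)
        model <- fw$model  # running BN statistics advance
        lo <- weighted_cross_entropy(fw$scores, y, cw, grad = TRUE)
        if (!is.finite(lo$loss))
          sg_stop("loss became non-finite at epoch %d, batch %d (lr %.3g)",
                  epoch, n_batches + 1L, lr_schedule(step, config))
        bw <- model_backward(model, fw$cache, lo$grad)
        up <- adam_step(params, bw$param_grads, state,
                        lr_schedule(step, config))
        params <- up$params; state <- up$state
        model <- model_set_params(model, params)
        step <- step + 1L
        ep_loss <- ep_loss + lo$loss
        n_batches <- n_batches + 1L
        pred <- scores_to_batch_mask(fw$scores)
        bc <- batch_iou_counts(pred, y, L)
        counts <- if (is.null(counts)) bc else counts + bc
      }
      list(loss = ep_loss / n_batches, miou = counts_to_miou(counts))
    })
    history[[epoch]] <- data.frame(epoch = epoch, step = step,
                                   lr = lr_schedule(step - 1L, config),
                                   loss = res$loss, miou = res$miou)
    if (config$verbose)
      message(sprintf("epoch %3d  loss %.4f  mIoU %.3f", epoch,
                      res$loss, res$miou))
    if (res$miou > best$miou) best <- list(miou = res$miou, params = params)
    if (!is.null(config$stop_miou) && res$miou >= config$stop_miou) break
  }

  best_model <- model_set_params(model, best$params)
  if (!is.null(config$checkpoint_path))
    save_checkpoint(best_model, config$checkpoint_path)
  list(model = best_model, final_model = model,
       history = do.call(rbind, history), best_miou = best$miou,
       class_weights = cw)
}

# argmax masks for a whole (H, W, L, N) score batch -> (H, W, N) array
scores_to_batch_mask <- function(scores) {
  d <- dim(scores)
  out <- array(0L, dim = d[c(1, 2, 4)])
  for (n in seq_len(d[4]))
    out[, , n] <- scores_to_mask(scores[, , , n, drop = FALSE])
  out
}

#' Load an image/annotation dataset from a manifest
#'
#' Reads each image PNG and rasterizes its annotation into a label mask:
#' polylines as strokes (`task = "lines"`, classes background/line) or
#' keypoints as class-labelled discs (`task = "keypoints"`, classes
#' background/paddy/millet).
#'
#' @param manifest path to a TSV manifest (see [generate_dataset()]).
#' @param task `"lines"` or `"keypoints"`.
#' @param thickness stroke thickness for the line task.
#' @return list of `list(image, mask, graphic)` entries.
#' @export
load_dataset <- function(manifest, task = c("lines", "keypoints"),
                         thickness = 5) {
  task <- match.arg(task)
  m <- read_manifest(manifest)
  lapply(seq_len(nrow(m)), function(i) {
    img <- read_png(m$image[i])
    g <- read_annotation(m$annotation[i])
    mask <- if (task == "lines") rasterize_lines(g, thickness)
            else rasterize_keypoints(g)
    list(image = img, mask = mask, graphic = g)
  })
}
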