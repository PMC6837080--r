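# Class-weighted pixel-wise cross-entropy.

# Numerically stable log-softmax over the class axis of (H, W, L, N) scores;
# returns list(logp, p) with the same shape.
softmax_log <- function(scores) {
  d <- dim(scores)
  L <- d[3]
  sm <- scores; dim(sm) <- c(d[1] * d[2], L, d[4])
  m <- sm[, 1, , drop = FALSE]
  for (l in seq_len(L)[-1]) m <- pmax(m, sm[, l, , drop = FALSE])
  z <- sm
  for (l in seq_len(L)) z[, l, ] <- sm[, l, ] - m[, 1, ]
  ez <- exp(z)
  s <- ez[, 1, , drop = FALSE]
  for (l in seq_len(L)[-1]) s <- s + ez[, l, , drop = FALSE]
  logp <- z
  for (l in seq_len(L)) logp[, l, ] <- z[, l, ] - log(s[, 1, ])
  p <- exp(logp)
  dim(logp) <- d; dim(p) <- d
  list(logp = logp, p = p)
}

#' Class-weighted pixel-wise cross-entropy loss
#'
#' `loss = -(1/N) * sum_i w[y_i] * log p[y_i]`, with `p` the softmax of the
#' class scores and `N` the total pixel count of the batch.  With unit
#' weights this is the plain pixel-wise cross-entropy; the weights counter
#' class imbalance (see [compute_class_weights()]).
#'
#' @param scores class scores `(H, W, L, N)` (or `(H, W, L)`).
#' @param target integer label array `(H, W, N)` (or an `(H, W)` matrix),
#'   values in `0 .. L-1`.
#' @param weights numeric vector of `L` positive class weights
#'   (background first); default all ones.
#' @param grad also return the gradient of the loss w.r.t. `scores`.
#' @return the scalar loss, or (with `grad = TRUE`) a list
#'   `(loss, grad)` where `grad` has the shape of `scores`.
#' @export
weighted_cross_entropy <- function(scores, target, weights = NULL,
                                   grad = FALSE) {
  if (length(dim(scores)) == 3) dim(scores) <- c(dim(scores), 1L)
  if (is.matrix(target)) dim(target) <- c(dim(target), 1L)
  d <- dim(scores)
  L <- d[3]
  sg_check(all(dim(target) == d[c(1, 2, 4)]),
           "scores and target are not spatially aligned")
  sg_check(all(target >= 0), "negative class index in target")
  sg_check(max(target) < L,
           "target contains class index %d but scores have %d classes",
           max(target), L)
  weights <- weights %||% rep(1, L)
  sg_check(length(weights) == L && all(weights > 0) && all(is.finite(weights)),
           "weights must be %d positive finite values", L)

  sl <- softmax_log(scores)
  HW <- d[1] * d[2]
  # linear index of the true-class entry for every pixel of every sample
  pix <- rep(seq_len(HW), times = d[4])
  smp <- rep(seq_len(d[4]) - 1L, each = HW)
  true_idx <- pix + HW * as.integer(target) + HW * L * smp
  wv <- weights[as.integer(target) + 1L]
  N <- HW * d[4]
  loss <- -sum(wv * sl$logp[true_idx]) / N
  if (!grad) return(loss)

  g <- sl$p
  dim(g) <- c(HW, L, d[4])
  wm <- wv; dim(wm) <- c(HW, d[4])
  for (l in seq_len(L)) g[, l, ] <- g[, l, ] * wm
  dim(g) <- d
  g[true_idx] <- g[true_idx] - wv
  list(loss = loss, grad = g / N)
}
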