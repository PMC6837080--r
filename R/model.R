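# Explicit computational graph for the encoder--decoder.
#
# A model is a DAG of typed nodes (conv / bn / relu / pool / up / concat /
# add / input) stored in topological order; forward evaluation caches the
# per-node values needed by the hand-derived backward pass.  No external
# deep-learning framework is involved: convolution, pooling and
# up-sampling run through the compiled im2col kernels, batch
# normalization and the reductions are vectorized R.

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.9

new_graph_builder <- function() {
  env <- new.env(parent = emptyenv())
  env$nodes <- list()
  env$channels <- integer()
  env
}

add_node <- function(gb, node, channels) {
  # force both promises first: nested gb_* calls in the arguments must
  # register their own nodes before this one takes an id
  force(node); force(channels)
  id <- length(gb$nodes) + 1L
  node$id <- id
  gb$nodes[[id]] <- node
  gb$channels[id] <- channels
  id
}

xavier_conv <- function(kh, kw, cin, cout) {
  fan_in <- kh * kw * cin
  fan_out <- kh * kw * cout
  a <- sqrt(6 / (fan_in + fan_out))
  array(runif(kh * kw * cin * cout, -a, a), dim = c(kh, kw, cin, cout))
}

gb_conv <- function(gb, input, kh, kw, cout) {
  cin <- gb$channels[input]
  add_node(gb, list(op = "conv", inputs = input,
                    W = xavier_conv(kh, kw, cin, cout),
                    b = numeric(cout)), cout)
}

gb_bn <- function(gb, input) {
  C <- gb$channels[input]
  add_node(gb, list(op = "bn", inputs = input,
                    gamma = rep(1, C), beta = numeric(C),
                    running_mean = numeric(C), running_var = rep(1, C)), C)
}

gb_relu <- function(gb, input)
  add_node(gb, list(op = "relu", inputs = input), gb$channels[input])

gb_pool <- function(gb, input)
  add_node(gb, list(op = "pool", inputs = input), gb$channels[input])

gb_up <- function(gb, input)
  add_node(gb, list(op = "up", inputs = input), gb$channels[input])

gb_concat <- function(gb, inputs)
  add_node(gb, list(op = "concat", inputs = inputs),
           sum(gb$channels[inputs]))

gb_add <- function(gb, inputs)
  add_node(gb, list(op = "add", inputs = inputs), gb$channels[inputs[1]])

# conv -> bn -> relu
gb_cbr <- function(gb, input, kh, kw, cout) {
  id <- gb_conv(gb, input, kh, kw, cout)
  id <- gb_bn(gb, id)
  gb_relu(gb, id)
}

# Large-kernel convolution, optionally factored k x 1 then 1 x k.
gb_large_conv <- function(gb, input, k, cout, separable) {
  if (separable && k > 1) {
    id <- gb_conv(gb, input, k, 1L, cout)
    gb_conv(gb, id, 1L, k, cout)
  } else {
    gb_conv(gb, input, k, k, cout)
  }
}

# Extended skip module: channel-preserving 1x1 path concatenated with the
# element-wise sum of per-kernel separable branches (skip_branch_channels
# maps each), followed by ReLU.  Output channels = Cin + skip_branch_channels.
gb_skip_module <- function(gb, input, kernels, branch_ch) {
  cin <- gb$channels[input]
  p1 <- gb_conv(gb, input, 1L, 1L, cin)
  branches <- vapply(kernels, function(k)
    gb_large_conv(gb, input, k, branch_ch, separable = TRUE), 0L)
  merged <- if (length(branches) > 1) gb_add(gb, branches) else branches[1]
  gb_relu(gb, gb_concat(gb, c(p1, merged)))
}

#' Build an extended-skip encoder--decoder model
#'
#' Instantiates the network described by a [net_config()] as an explicit
#' computational graph with Xavier-initialized (uniform Glorot) weights.
#' All four ablation variants (no skip, fixed identity skip, single-scale
#' learned skip, multi-scale filter-bank skip; large tail kernels on or
#' off via `tail_blocks` / `tail_kernel`) come from configuration alone.
#'
#' @param config a [net_config()].
#' @param seed optional integer; when given, initialization is performed
#'   under this seed without disturbing the caller's RNG stream.
#' @return an object of class `sg_model`.
#' @export
build_model <- function(config, seed = NULL) {
  validate_net_config(config)
  if (!is.null(seed)) return(sg_with_seed(seed, build_model(config)))

  gb <- new_graph_builder()
  input <- add_node(gb, list(op = "input", inputs = integer()),
                    config$in_channels)
  n_stages <- length(config$encoder_stages)
  stage_out <- integer(n_stages)
  cur <- input
  for (s in seq_len(n_stages)) {
    st <- config$encoder_stages[[s]]
    for (j in seq_len(st[1])) cur <- gb_cbr(gb, cur, 3L, 3L, st[2])
    stage_out[s] <- cur
    if (s < n_stages) cur <- gb_pool(gb, cur)
  }

  tail_ch <- gb$channels[cur]
  for (t in seq_len(config$tail_blocks)) {
    cur <- gb_large_conv(gb, cur, config$tail_kernel, tail_ch,
                         config$tail_separable)
    cur <- gb_bn(gb, cur)
    cur <- gb_relu(gb, cur)
  }

  skip_ids <- rep(NA_integer_, n_stages)
  if (config$skip_mode != "none" && n_stages > 1) {
    for (s in seq_len(n_stages - 1)) {
      skip_ids[s] <- switch(config$skip_mode,
        fixed = stage_out[s],
        single_scale = gb_skip_module(gb, stage_out[s], config$single_scale_k,
                                      config$skip_branch_channels),
        multiscale = gb_skip_module(gb, stage_out[s], config$multiscale_kernels,
                                    config$skip_branch_channels))
    }
  }

  for (s in rev(seq_len(n_stages - 1))) {
    cur <- gb_up(gb, cur)
    if (!is.na(skip_ids[s])) cur <- gb_concat(gb, c(cur, skip_ids[s]))
    for (j in seq_len(config$decoder_convs))
      cur <- gb_cbr(gb, cur, 3L, 3L, config$decoder_channels)
  }
  out <- gb_conv(gb, cur, 1L, 1L, config$n_classes)

  structure(list(config = config, nodes = gb$nodes, channels = gb$channels,
                 input_id = input, output_id = out),
            class = "sg_model")
}

#' @export
print.sg_model <- function(x, ...) {
  cat(sprintf("<sg_model> %d nodes, %s parameters, skip '%s', %d classes\n",
              length(x$nodes), format(count_parameters(x), big.mark = ","),
              x$config$skip_mode, x$config$n_classes))
  invisible(x)
}

#' Count trainable parameters
#'
#' Exact count of trainable weights (convolution kernels and biases,
#' batch-norm scale and shift; running statistics excluded).
#'
#' @param model an [build_model()] result.
#' @return integer parameter count.
#' @export
count_parameters <- function(model) {
  sum(vapply(model$nodes, function(nd) {
    length(nd$W) + length(nd$b) + length(nd$gamma) + length(nd$beta)
  }, 0))
}

# ---- forward ---------------------------------------------------------------

bn_channel_stats <- function(x) {
  d <- dim(x)
  xm <- x; dim(xm) <- c(d[1] * d[2], d[3], d[4])
  xm
}

node_forward <- function(nd, ins, training) {
  switch(nd$op,
    input = list(out = ins[[1]]),
    conv = {
      list(out = cpp_conv2d_forward(ins[[1]], nd$W, nd$b), x = ins[[1]])
    },
    bn = {
      x <- ins[[1]]
      d <- dim(x)
      xm <- x; dim(xm) <- c(d[1] * d[2], d[3], d[4])
      C <- d[3]; M <- d[1] * d[2] * d[4]
      out <- xm
      if (training) {
        mu <- numeric(C); va <- numeric(C); xhat <- xm; ivar <- numeric(C)
        for (c in seq_len(C)) {
          xc <- xm[, c, ]
          mu[c] <- mean(xc)
          va[c] <- sum((xc - mu[c])^2) / M
          ivar[c] <- 1 / sqrt(va[c] + BN_EPS)
          xh <- (xc - mu[c]) * ivar[c]
          xhat[, c, ] <- xh
          out[, c, ] <- nd$gamma[c] * xh + nd$beta[c]
        }
        dim(out) <- d
        list(out = out, xhat = xhat, ivar = ivar, mu = mu, va = va)
      } else {
        for (c in seq_len(C)) {
          sc <- nd$gamma[c] / sqrt(nd$running_var[c] + BN_EPS)
          out[, c, ] <- (xm[, c, ] - nd$running_mean[c]) * sc + nd$beta[c]
        }
        dim(out) <- d
        list(out = out)
      }
    },
    relu = {
      x <- ins[[1]]
      list(out = pmax(x, 0), mask = x > 0)
    },
    pool = {
      r <- cpp_maxpool2_forward(ins[[1]])
      list(out = r$out, idx = r$idx, xdim = dim(ins[[1]]))
    },
    up = list(out = cpp_upsample2_forward(ins[[1]])),
    concat = {
      chs <- vapply(ins, function(a) dim(a)[3], 0L)
      d <- dim(ins[[1]])
      out <- array(0, dim = c(d[1], d[2], sum(chs), d[4]))
      at <- 0L
      for (a in ins) {
        ca <- dim(a)[3]
        out[, , at + seq_len(ca), ] <- a
        at <- at + ca
      }
      list(out = out, chs = chs)
    },
    add = list(out = Reduce(`+`, ins)),
    sg_stop("unknown op '%s'", nd$op)
  )
}

#' Run a forward pass
#'
#' @param model an `sg_model`.
#' @param x input batch `(H, W, C, N)` (or a single `(H, W, C)` image);
#'   the spatial size must be divisible by `2^(n_stages - 1)`.
#' @param training logical; `TRUE` uses batch statistics in batch norm
#'   (and updates running statistics), `FALSE` uses running statistics.
#' @param keep_cache keep per-node activations for [model_backward()].
#' @return class scores `(H, W, n_classes, N)`; when `keep_cache = TRUE`, a
#'   list `(scores, cache, model)` (the returned model carries updated
#'   batch-norm running statistics).
#' @export
model_forward <- function(model, x, training = FALSE, keep_cache = FALSE) {
  x <- as_batch(x)
  d <- dim(x)
  pf <- pool_factor(model$config)
  sg_check(d[1] %% pf == 0 && d[2] %% pf == 0,
           "input spatial size (%d, %d) must be divisible by %d", d[1], d[2], pf)
  sg_check(d[3] == model$config$in_channels,
           "input has %d channels, model expects %d", d[3],
           model$config$in_channels)

  vals <- vector("list", length(model$nodes))
  caches <- if (keep_cache) vector("list", length(model$nodes))
  for (i in seq_along(model$nodes)) {
    nd <- model$nodes[[i]]
    ins <- if (nd$op == "input") list(x) else vals[nd$inputs]
    r <- node_forward(nd, ins, training)
    vals[[i]] <- r$out
    if (training && nd$op == "bn") {
      model$nodes[[i]]$running_mean <-
        BN_MOMENTUM * nd$running_mean + (1 - BN_MOMENTUM) * r$mu
      model$nodes[[i]]$running_var <-
        BN_MOMENTUM * nd$running_var + (1 - BN_MOMENTUM) * r$va
    }
    if (keep_cache) {
      r$out_dim <- dim(r$out)
      caches[[i]] <- r
    }
  }
  scores <- vals[[model$output_id]]
  if (!keep_cache) return(scores)
  list(scores = scores, cache = caches, model = model)
}

# ---- backward --------------------------------------------------------------

# Backpropagate dscores through the graph.  Returns gradients keyed
# "n<id>.<param>" plus the gradient w.r.t. the input.
model_backward <- function(model, cache, dscores) {
  n <- length(model$nodes)
  gout <- vector("list", n)
  gout[[model$output_id]] <- dscores
  pgrads <- list()
  dx_input <- NULL
  for (i in rev(seq_len(n))) {
    g <- gout[[i]]
    if (is.null(g)) next
    nd <- model$nodes[[i]]
    ca <- cache[[i]]
    push <- function(j, gj) {
      gout[[j]] <<- if (is.null(gout[[j]])) gj else gout[[j]] + gj
    }
    switch(nd$op,
      input = { dx_input <- g },
      conv = {
        r <- cpp_conv2d_backward(ca$x, nd$W, g)
        pgrads[[sprintf("n%d.W", i)]] <- r$dw
        pgrads[[sprintf("n%d.b", i)]] <- r$db
        push(nd$inputs, r$dx)
      },
      bn = {
        d <- ca$out_dim
        C <- d[3]; M <- d[1] * d[2] * d[4]
        gm <- g; dim(gm) <- c(d[1] * d[2], C, d[4])
        dgamma <- numeric(C); dbeta <- numeric(C)
        dx <- gm
        for (c in seq_len(C)) {
          gc <- gm[, c, ]
          xh <- ca$xhat[, c, ]
          dgamma[c] <- sum(gc * xh)
          dbeta[c] <- sum(gc)
          dxh <- gc * nd$gamma[c]
          dx[, c, ] <- (ca$ivar[c] / M) *
            (M * dxh - sum(dxh) - xh * sum(dxh * xh))
        }
        dim(dx) <- d
        pgrads[[sprintf("n%d.gamma", i)]] <- dgamma
        pgrads[[sprintf("n%d.beta", i)]] <- dbeta
        push(nd$inputs, dx)
      },
      relu = push(nd$inputs, g * ca$mask),
      pool = push(nd$inputs, cpp_maxpool2_backward(g, ca$idx, ca$xdim)),
      up = push(nd$inputs, cpp_upsample2_backward(g)),
      concat = {
        at <- 0L
        for (k in seq_along(nd$inputs)) {
          ck <- ca$chs[k]
          push(nd$inputs[k], g[, , at + seq_len(ck), , drop = FALSE])
          at <- at + ck
        }
      },
      add = for (j in nd$inputs) push(j, g)
    )
  }
  list(param_grads = pgrads, dx = dx_input)
}

# ---- parameter access ------------------------------------------------------

model_params <- function(model) {
  out <- list()
  for (nd in model$nodes) {
    for (p in c("W", "b", "gamma", "beta")) {
      if (!is.null(nd[[p]])) out[[sprintf("n%d.%s", nd$id, p)]] <- nd[[p]]
    }
  }
  out
}

model_set_params <- function(model, params) {
  for (key in names(params)) {
    m <- regmatches(key, regexec("^n([0-9]+)\\.(.+)$", key))[[1]]
    id <- as.integer(m[2]); field <- m[3]
    val <- params[[key]]
    old <- model$nodes[[id]][[field]]
    if (!is.null(dim(old))) dim(val) <- dim(old)
    model$nodes[[id]][[field]] <- val
  }
  model
}

#' Save and load model checkpoints
#'
#' Checkpoints are self-describing: the serialized object embeds the
#' [net_config()] alongside all weights and batch-norm running statistics,
#' so `load_checkpoint()` rebuilds the model without external context.
#'
#' @param model an `sg_model`.
#' @param path checkpoint file (RDS).
#' @return `load_checkpoint()` returns the restored `sg_model`.
#' @export
save_checkpoint <- function(model, path) {
  running <- lapply(model$nodes, function(nd)
    if (nd$op == "bn") list(mean = nd$running_mean, var = nd$running_var))
  saveRDS(list(format = "semgraphics-checkpoint-1",
               config = model$config,
               params = model_params(model),
               running = running), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  sg_check(identical(ck$format, "semgraphics-checkpoint-1"),
           "'%s' is not a semgraphics checkpoint", path)
  model <- build_model(ck$config, seed = 0L)
  model <- model_set_params(model, ck$params)
  for (i in seq_along(ck$running)) {
    if (!is.null(ck$running[[i]])) {
      model$nodes[[i]]$running_mean <- ck$running[[i]]$mean
      model$nodes[[i]]$running_var <- ck$running[[i]]$var
    }
  }
  model
}

#' Predict label masks
#'
#' Forward pass in evaluation mode followed by per-pixel argmax over the
#' class scores.
#'
#' @param model an `sg_model` (other classes may provide methods, e.g.
#'   oracle models in tests).
#' @param x input image `(H, W, C)` or batch `(H, W, C, N)`.
#' @return an integer label mask matrix for a single image, or a list of
#'   them for a batch.
#' @export
model_predict <- function(model, x) UseMethod("model_predict")

#' @rdname model_predict
#' @export
model_predict.sg_model <- function(model, x) {
  single <- length(dim(x)) == 3
  scores <- model_forward(model, x, training = FALSE)
  masks <- lapply(seq_len(dim(scores)[4]), function(n)
    scores_to_mask(scores[, , , n, drop = FALSE]))
  if (single) masks[[1]] else masks
}

# argmax over the class axis of a single-image score array -> 0-based mask
scores_to_mask <- function(scores) {
  d <- dim(scores)
  sm <- scores; dim(sm) <- c(d[1] * d[2], d[3])
  mask <- max.col(sm, ties.method = "first") - 1L
  matrix(as.integer(mask), d[1], d[2])
}
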