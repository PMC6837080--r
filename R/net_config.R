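#' Declarative network architecture configuration
#'
#' Describes the extended-skip encoder--decoder and all its ablation
#' variants, so that every architecture studied (fixed UNet-style skips,
#' large tail kernels on/off, single- vs multi-scale skip filter banks)
#' is constructible from configuration alone.
#'
#' The encoder is a stack of VGG-style stages (`convs_per_block` 3x3
#' convolutions, each followed by batch normalization and ReLU), with 2x2
#' max pooling between stages, and ends in `tail_blocks` large-kernel
#' blocks that widen the receptive field.  Large kernels are factored into
#' k x 1 and 1 x k separable passes when `tail_separable`.  The decoder
#' mirrors the encoder at a constant width (`decoder_channels`), merging
#' encoder features through the configured skip connection at each level,
#' and ends in a linear 1x1 convolution to `n_classes` score channels.
#'
#' Skip modes: `"none"` (no skip), `"fixed"` (identity copy-and-concatenate),
#' `"single_scale"` (a learned filter bank with one kernel size
#' `single_scale_k`), `"multiscale"` (a learned 1x1 channel-preserving path
#' plus parallel separable branches of sizes `multiscale_kernels`, each
#' emitting `skip_branch_channels` feature maps that are merged by
#' element-wise sum, for `Cin + skip_branch_channels` output channels).
#'
#' Defaults approximate the published design where exact widths are not
#' available: 4 encoder stages of 2 convolutions (32/64/128/256 channels),
#' two separable tail blocks of kernel 15, skip branches of 12 channels at
#' scales 7/11/15, decoder width 64.
#'
#' @param encoder_stages list of `c(convs_per_block, channels)` per stage.
#' @param tail_blocks number of large-kernel blocks at the encoder tail.
#' @param tail_kernel odd kernel size of the tail blocks.
#' @param tail_separable factor tail kernels into k x 1 + 1 x k passes.
#' @param skip_mode one of `"multiscale"`, `"fixed"`, `"single_scale"`,
#'   `"none"`.
#' @param single_scale_k odd kernel size used when `skip_mode = "single_scale"`.
#' @param multiscale_kernels odd kernel sizes of the multi-scale branches.
#' @param skip_branch_channels feature maps emitted by each learned skip
#'   branch (constant, default 12).
#' @param decoder_channels constant decoder width.
#' @param decoder_convs 3x3 convolutions per decoder level.
#' @param n_classes number of target classes including background (>= 2).
#' @param in_channels input image channels.
#' @return an object of class `net_config`.
#' @export
net_config <- function(encoder_stages = list(c(2, 32), c(2, 64), c(2, 128), c(2, 256)),
                       tail_blocks = 2, tail_kernel = 15, tail_separable = TRUE,
                       skip_mode = c("multiscale", "fixed", "single_scale", "none"),
                       single_scale_k = 7, multiscale_kernels = c(7, 11, 15),
                       skip_branch_channels = 12, decoder_channels = 64,
                       decoder_convs = 2, n_classes = 2, in_channels = 3) {
  skip_mode <- match.arg(skip_mode)
  cfg <- list(encoder_stages = lapply(encoder_stages, as.integer),
              tail_blocks = as.integer(tail_blocks),
              tail_kernel = as.integer(tail_kernel),
              tail_separable = isTRUE(tail_separable),
              skip_mode = skip_mode,
              single_scale_k = as.integer(single_scale_k),
              multiscale_kernels = as.integer(multiscale_kernels),
              skip_branch_channels = as.integer(skip_branch_channels),
              decoder_channels = as.integer(decoder_channels),
              decoder_convs = as.integer(decoder_convs),
              n_classes = as.integer(n_classes),
              in_channels = as.integer(in_channels))
  validate_net_config(cfg)
  structure(cfg, class = "net_config")
}

validate_net_config <- function(cfg) {
  sg_check(length(cfg$encoder_stages) >= 1, "encoder_stages must be non-empty")
  for (st in cfg$encoder_stages)
    sg_check(length(st) == 2 && st[1] >= 1 && st[2] >= 1,
             "each encoder stage must be c(convs_per_block, channels)")
  sg_check(cfg$n_classes >= 2, "n_classes must be >= 2")
  sg_check(is_odd(cfg$tail_kernel) && cfg$tail_kernel >= 1,
           "tail_kernel must be odd and >= 1")
  sg_check(is_odd(cfg$single_scale_k) && cfg$single_scale_k >= 1,
           "single_scale_k must be odd and >= 1")
  sg_check(all(is_odd(cfg$multiscale_kernels)) && all(cfg$multiscale_kernels >= 1),
           "multiscale_kernels must all be odd and >= 1")
  if (cfg$skip_mode %in% c("multiscale", "single_scale"))
    sg_check(cfg$skip_branch_channels > 0,
             "skip_branch_channels must be > 0 for learned skips")
  sg_check(cfg$decoder_channels >= 1 && cfg$decoder_convs >= 1,
           "decoder_channels and decoder_convs must be >= 1")
  invisible(cfg)
}

#' @export
print.net_config <- function(x, ...) {
  st <- paste(vapply(x$encoder_stages, function(s)
    sprintf("%dx(3x3,%d)", s[1], s[2]), ""), collapse = " -> ")
  cat(sprintf("<net_config> encoder %s | tail %d x k=%d%s | skip %s | decoder %d | classes %d\n",
              st, x$tail_blocks, x$tail_kernel,
              if (x$tail_separable) " (separable)" else "",
              x$skip_mode, x$decoder_channels, x$n_classes))
  invisible(x)
}

# Pooling factor the input spatial size must divide by.
pool_factor <- function(cfg) 2L^(length(cfg$encoder_stages) - 1L)
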