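# Paired image/mask augmentation.
#
# Geometric transforms are applied identically to image and mask (bilinear
# vs nearest-neighbour sampling), photometric jitter to the image only.
# Fixed application order: scale, rotation, horizontal mirror, photometric
# jitter, random crop.

#' Augmentation specification
#'
#' Ranges follow the published settings for the line task: scale factor
#' sampled in `[0.5, 1.5]`, rotation in `[-15, 15]` degrees, random
#' left--right mirroring, brightness/saturation distortion, and a random
#' crop of `crop_size`.  Distortion magnitudes are not published; the
#' +/- 20 % defaults are configurable.
#'
#' @param scale_range `(low, high)` multiplicative scale range.
#' @param rotation_range max absolute rotation, degrees.
#' @param hflip_prob probability of a horizontal (left--right) mirror.
#' @param brightness_delta max absolute additive brightness shift (fraction).
#' @param saturation_delta max absolute saturation distortion (fraction).
#' @param crop_size side of the random square crop, px.
#' @return an object of class `aug_spec`.
#' @export
aug_spec <- function(scale_range = c(0.5, 1.5), rotation_range = 15,
                     hflip_prob = 0.5, brightness_delta = 0.2,
                     saturation_delta = 0.2, crop_size = 512) {
  sg_check(scale_range[1] <= scale_range[2] && scale_range[1] > 0,
           "scale_range must be 0 < low <= high")
  sg_check(rotation_range >= 0 && hflip_prob >= 0 && hflip_prob <= 1,
           "invalid rotation_range or hflip_prob")
  structure(list(scale_range = as.numeric(scale_range),
                 rotation_range = as.numeric(rotation_range),
                 hflip_prob = as.numeric(hflip_prob),
                 brightness_delta = as.numeric(brightness_delta),
                 saturation_delta = as.numeric(saturation_delta),
                 crop_size = as.integer(crop_size)),
            class = "aug_spec")
}

# Inverse-mapped affine warp.  A maps output (row, col) to source (row, col)
# (both 0-based).  interp: "bilinear" (image planes) or "nearest" (masks).
warp_affine <- function(x, A, out_h, out_w, interp = "bilinear", fill = 0) {
  is_mask <- is.null(dim(x)) || length(dim(x)) == 2
  H <- nrow(x); W <- if (is_mask) ncol(x) else dim(x)[2]
  rr <- rep(seq_len(out_h) - 1, times = out_w)
  cc <- rep(seq_len(out_w) - 1, each = out_h)
  sr <- A[1, 1] * rr + A[1, 2] * cc + A[1, 3]
  sc <- A[2, 1] * rr + A[2, 2] * cc + A[2, 3]
  if (interp == "nearest") {
    ir <- round(sr); ic <- round(sc)
    ok <- ir >= 0 & ir <= H - 1 & ic >= 0 & ic <= W - 1
    out <- matrix(fill, out_h, out_w)
    out[ok] <- x[cbind(ir[ok] + 1, ic[ok] + 1)]
    storage.mode(out) <- storage.mode(x)
    return(out)
  }
  r0 <- floor(sr); c0 <- floor(sc)
  fr <- sr - r0; fc <- sc - c0
  ok <- r0 >= 0 & r0 <= H - 1 & c0 >= 0 & c0 <= W - 1
  r1 <- pmin(r0 + 1, H - 1); c1 <- pmin(c0 + 1, W - 1)
  planes <- if (is_mask) 1L else dim(x)[3]
  out <- array(fill, dim = c(out_h, out_w, planes))
  for (ch in seq_len(planes)) {
    xp <- if (is_mask) x else x[, , ch]
    v <- rep(fill, out_h * out_w)
    i00 <- cbind(r0[ok] + 1, c0[ok] + 1); i01 <- cbind(r0[ok] + 1, c1[ok] + 1)
    i10 <- cbind(r1[ok] + 1, c0[ok] + 1); i11 <- cbind(r1[ok] + 1, c1[ok] + 1)
    v[ok] <- xp[i00] * (1 - fr[ok]) * (1 - fc[ok]) +
             xp[i01] * (1 - fr[ok]) * fc[ok] +
             xp[i10] * fr[ok] * (1 - fc[ok]) +
             xp[i11] * fr[ok] * fc[ok]
    out[, , ch] <- v
  }
  if (is_mask) out[, , 1] else out
}

#' Augment an image/mask pair
#'
#' Applies, in order: random scale, random rotation about the image
#' centre, random horizontal mirror, photometric jitter (image only) and
#' a random crop of `spec$crop_size`.  The identical geometric transform
#' is applied to image (bilinear) and mask (nearest neighbour), so mask
#' values remain valid class indices.  If the post-scale image is smaller
#' than the crop, it is padded with background before cropping.  All
#' randomness comes from the caller's RNG stream, and the number of draws
#' is independent of the sampled values, so a seeded stream reproduces
#' the augmentation exactly.
#'
#' @param image numeric array `(H, W, 3)` in `[0, 1]`.
#' @param mask integer label matrix `(H, W)`.
#' @param spec an [aug_spec()].
#' @return list `(image, mask, params)`; `params` records the sampled
#'   scale, angle, flip and jitter values.
#' @export
augment_pair <- function(image, mask, spec) {
  sg_check(all(dim(image)[1:2] == dim(mask)), "image and mask misaligned")
  # sample every parameter up front, in fixed order
  s <- runif(1, spec$scale_range[1], spec$scale_range[2])
  ang <- runif(1, -spec$rotation_range, spec$rotation_range)
  u_flip <- runif(1)
  b <- runif(1, -spec$brightness_delta, spec$brightness_delta)
  sat <- runif(1, -spec$saturation_delta, spec$saturation_delta)
  u_crop <- runif(2)

  H <- dim(image)[1]; W <- dim(image)[2]
  oh <- max(1L, as.integer(round(s * H)))
  ow <- max(1L, as.integer(round(s * W)))

  if (s != 1 || ang != 0) {
    th <- ang * pi / 180
    # output -> source: undo rotation about the output centre, then scale
    cr <- (oh - 1) / 2; cc <- (ow - 1) / 2
    R <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2, byrow = TRUE)
    # source = (R^T (out - centre)) / s + source_centre
    A <- matrix(0, 2, 3)
    A[, 1:2] <- t(R) / s
    A[, 3] <- c((H - 1) / 2, (W - 1) / 2) - A[, 1:2] %*% c(cr, cc)
    image <- warp_affine(image, A, oh, ow, "bilinear")
    mask <- warp_affine(mask, A, oh, ow, "nearest")
  }

  if (u_flip < spec$hflip_prob) {
    image <- image[, rev(seq_len(dim(image)[2])), , drop = FALSE]
    mask <- mask[, rev(seq_len(ncol(mask))), drop = FALSE]
  }

  if (b != 0 || sat != 0) {
    grey <- (image[, , 1] + image[, , 2] + image[, , 3]) / 3
    for (ch in 1:3)
      image[, , ch] <- grey + (1 + sat) * (image[, , ch] - grey) + b
    image <- pmin(pmax(image, 0), 1)
  }

  cs <- spec$crop_size
  ch_now <- dim(image)[1]; cw_now <- dim(image)[2]
  if (ch_now < cs || cw_now < cs) {
    pi_ <- array(0, dim = c(max(cs, ch_now), max(cs, cw_now), 3))
    pm <- matrix(0L, max(cs, ch_now), max(cs, cw_now))
    pi_[seq_len(ch_now), seq_len(cw_now), ] <- image
    pm[seq_len(ch_now), seq_len(cw_now)] <- mask
    image <- pi_; mask <- pm
    ch_now <- dim(image)[1]; cw_now <- dim(image)[2]
  }
  r_off <- floor(u_crop[1] * (ch_now - cs + 1))
  c_off <- floor(u_crop[2] * (cw_now - cs + 1))
  image <- image[r_off + seq_len(cs), c_off + seq_len(cs), , drop = FALSE]
  mask <- mask[r_off + seq_len(cs), c_off + seq_len(cs), drop = FALSE]

  list(image = image, mask = mask,
       params = list(scale = s, angle = ang, flipped = u_flip < spec$hflip_prob,
                     brightness = b, saturation = sat,
                     crop = c(r_off, c_off)))
}
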