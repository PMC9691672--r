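# Ground-truth preparation: normalized images, refined (border-removed,
# eroded) binary masks, per-nucleus normalized Euclidean distance maps,
# one-hot class masks, and seeded augmentation.

#' Normalize integer image intensities to [0, 1]
#'
#' @param raw Integer-valued image array (any shape) with values in
#'   `[0, max_value]`.
#' @param max_value Maximum representable value (255 for 8-bit).
#' @export
normalize_intensity <- function(raw, max_value = 255L) {
  if (max_value <= 0) stop("max_value must be positive")
  if (any(raw < 0) || any(raw > max_value))
    stop(sprintf("raw intensities must lie in [0, %d]", max_value))
  raw / max_value
}

# Pixels whose 8-neighborhood contains a different nonzero label.
touching_border_pixels <- function(labels) {
  h <- nrow(labels); w <- ncol(labels)
  border <- matrix(FALSE, h, w)
  shifts <- list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L),
                 c(-1L, -1L), c(-1L, 1L), c(1L, -1L), c(1L, 1L))
  for (s in shifts) {
    nb <- matrix(0L, h, w)
    r_src <- max(1L, 1L + s[1L]):min(h, h + s[1L])
    c_src <- max(1L, 1L + s[2L]):min(w, w + s[2L])
    r_dst <- r_src - s[1L]; c_dst <- c_src - s[2L]
    nb[r_dst, c_dst] <- labels[r_src, c_src]
    border <- border | (labels > 0L & nb > 0L & nb != labels)
  }
  border
}

#' Refine an instance mask into a separated binary training target
#'
#' Two steps: (a) every pixel whose 8-neighborhood contains a different
#' nonzero instance label is set to background, so touching nuclei are
#' separated by at least a one-pixel gap; (b) binary erosion with a discrete
#' disk of radius `erosion_radius` (the 4-neighbor cross at radius 1). The
#' output foreground is a subset of the input foreground and no two distinct
#' input instances remain 8-connected. Instances that vanish entirely are
#' allowed and reported via a warning.
#'
#' @param labels Instance label mask (0 = background, contiguous ids 1..N).
#' @param erosion_radius Radius in pixels of the erosion disk (default 1).
#' @return Binary matrix with values in `{0, 1}`.
#' @export
refine_binary_mask <- function(labels, erosion_radius = 1L) {
  check_label_mask(labels)
  separated <- labels
  separated[touching_border_pixels(labels)] <- 0L
  fg <- (separated > 0L) * 1
  if (erosion_radius > 0L)
    fg <- as.matrix(EBImage::erode(fg, disk_brush(erosion_radius)))
  kept <- unique(as.integer(labels[fg > 0]))
  lost <- setdiff(label_ids(labels), kept)
  if (length(lost))
    warning(sprintf("instance(s) %s vanished during refinement",
                    paste(lost, collapse = ", ")))
  matrix(as.numeric(fg > 0), nrow(labels), ncol(labels))
}

#' Per-nucleus normalized Euclidean distance map
#'
#' For each instance independently, the Euclidean distance of each instance
#' pixel to the nearest non-instance pixel, divided by the instance maximum
#' so every instance peaks at exactly 1; background is 0 and single-pixel
#' instances get 1.
#'
#' @param labels Instance label mask.
#' @return Matrix of values in `[0, 1]`.
#' @export
make_distance_map <- function(labels) {
  check_label_mask(labels)
  out <- matrix(0, nrow(labels), ncol(labels))
  for (k in label_ids(labels)) {
    mk <- labels == k
    bb <- mask_bbox(mk)
    sub <- mk[bb$rows, bb$cols, drop = FALSE]
    # pad so instances touching the image edge still see background
    padded <- matrix(FALSE, length(bb$rows) + 2L, length(bb$cols) + 2L)
    padded[2:(nrow(padded) - 1L), 2:(ncol(padded) - 1L)] <- sub
    d <- as.matrix(EBImage::distmap(padded * 1))
    d <- d[2:(nrow(padded) - 1L), 2:(ncol(padded) - 1L), drop = FALSE]
    mx <- max(d)
    if (mx > 0) {
      vals <- d / mx
      sel <- which(sub)
      tmp <- out[bb$rows, bb$cols, drop = FALSE]
      tmp[sel] <- vals[sel]
      out[bb$rows, bb$cols] <- tmp
    }
  }
  out
}

#' One-hot class target from instance and class masks
#'
#' Channel 1 is the background indicator; channel `c + 1` marks the union of
#' instances of class `c`. The result is one-hot at every pixel.
#'
#' @param labels Instance label mask.
#' @param classes Class-code mask, constant within each instance, codes in
#'   `1..n_classes` on instance pixels.
#' @param n_classes Number of nucleus classes K.
#' @return H x W x (K+1) array in `{0, 1}`.
#' @export
make_class_onehot <- function(labels, classes, n_classes) {
  check_label_mask(labels)
  if (!identical(dim(labels), dim(classes)))
    stop("labels and classes must share one shape")
  for (k in label_ids(labels)) {
    ck <- unique(classes[labels == k])
    if (length(ck) != 1L)
      stop(sprintf("instance %d carries mixed class codes (%s)",
                   k, paste(sort(ck), collapse = ", ")))
    if (ck < 1L || ck > n_classes)
      stop(sprintf("instance %d has class %d outside 1..%d", k, ck, n_classes))
  }
  out <- array(0, c(dim(labels), n_classes + 1L))
  out[, , 1L] <- (labels == 0L) * 1
  for (c in seq_len(n_classes))
    out[, , c + 1L] <- (labels > 0L & classes == c) * 1
  out
}

#' Assemble a training sample from raw ground truth
#'
#' Bundles the normalized image with the refined binary mask, the distance
#' map (computed from the original labels, before erosion, so regression
#' peaks stay centred on full nuclei) and, when classes are given, the
#' one-hot class target.
#'
#' @param image H x W x 3 image in `[0, 1]`.
#' @param labels Instance label mask.
#' @param classes Optional class mask.
#' @param n_classes Number of classes when `classes` is given.
#' @param source_id Identifier carried through for provenance.
#' @export
prepare_sample <- function(image, labels, classes = NULL, n_classes = 0L,
                           source_id = NA_character_) {
  s <- list(image = image,
            refined_binary = suppressWarnings(refine_binary_mask(labels)),
            distance = make_distance_map(labels),
            labels = labels,
            source_id = source_id)
  if (!is.null(classes) && n_classes > 0L)
    s$class_onehot <- make_class_onehot(labels, classes, n_classes)
  class(s) <- "nucseg_sample"
  s
}

#' Augmentation configuration
#'
#' @param prob_hflip,prob_vflip Probabilities of horizontal / vertical flips.
#' @param prob_scale Probability of random scaling.
#' @param scale_range Scaling factor range (must be positive).
#' @param prob_contrast,contrast_range Probability and factor range of a
#'   contrast change about mid-gray.
#' @param prob_brightness,brightness_range Probability and additive range of
#'   a brightness shift.
#' @export
augment_config <- function(prob_hflip = 0.5, prob_vflip = 0.5,
                           prob_scale = 0.25, scale_range = c(0.8, 1.25),
                           prob_contrast = 0.25, contrast_range = c(0.8, 1.2),
                           prob_brightness = 0.25,
                           brightness_range = c(-0.1, 0.1)) {
  if (any(scale_range <= 0)) stop("scale_range must be positive")
  structure(list(prob_hflip = prob_hflip, prob_vflip = prob_vflip,
                 prob_scale = prob_scale, scale_range = scale_range,
                 prob_contrast = prob_contrast,
                 contrast_range = contrast_range,
                 prob_brightness = prob_brightness,
                 brightness_range = brightness_range),
            class = "augment_config")
}

scale_map <- function(x, s, nearest, pad_value = 0) {
  h <- nrow(x); w <- ncol(x)
  nh <- max(1L, round(h * s)); nw <- max(1L, round(w * s))
  y <- as.matrix(EBImage::resize(x, w = nh, h = nw,
                                 filter = if (nearest) "none" else "bilinear"))
  out <- matrix(pad_value, h, w)
  src_r <- if (nh >= h) (nh - h) %/% 2L + seq_len(h) else seq_len(nh)
  dst_r <- if (nh >= h) seq_len(h) else (h - nh) %/% 2L + seq_len(nh)
  src_c <- if (nw >= w) (nw - w) %/% 2L + seq_len(w) else seq_len(nw)
  dst_c <- if (nw >= w) seq_len(w) else (w - nw) %/% 2L + seq_len(nw)
  out[dst_r, dst_c] <- y[src_r, src_c]
  out
}

#' Augment a training sample
#'
#' Geometric transforms (flips, then scaling with center crop/pad back to
#' the original size) are applied identically to the image and to every
#' target; targets are resampled with nearest-neighbor interpolation, the
#' image bilinearly. Photometric transforms (contrast about 0.5, brightness
#' shift) touch the image only. Padded regions introduced by down-scaling
#' are white (1.0) in the image, background in all targets. Deterministic
#' under `seed`.
#'
#' @param sample A `nucseg_sample` from [prepare_sample()].
#' @param params An [augment_config()].
#' @param seed Integer seed.
#' @return The augmented `nucseg_sample`.
#' @export
augment_sample <- function(sample, params = augment_config(), seed = 1L) {
  stopifnot(inherits(sample, "nucseg_sample"),
            inherits(params, "augment_config"))
  with_seed(seed, {
    do_h <- stats::runif(1) < params$prob_hflip
    do_v <- stats::runif(1) < params$prob_vflip
    do_s <- stats::runif(1) < params$prob_scale
    s_fac <- stats::runif(1, params$scale_range[1L], params$scale_range[2L])
    do_c <- stats::runif(1) < params$prob_contrast
    c_fac <- stats::runif(1, params$contrast_range[1L], params$contrast_range[2L])
    do_b <- stats::runif(1) < params$prob_brightness
    b_sh <- stats::runif(1, params$brightness_range[1L],
                         params$brightness_range[2L])
  })
  out <- sample
  geom_mat <- function(x, nearest, pad_value = 0) {
    if (do_h) x <- flip_horizontal(x)
    if (do_v) x <- flip_vertical(x)
    if (do_s) x <- scale_map(x, s_fac, nearest, pad_value)
    x
  }
  img <- out$image
  for (ch in 1:3) img[, , ch] <- geom_mat(img[, , ch], FALSE, 1)
  out$refined_binary <- geom_mat(out$refined_binary, TRUE, 0)
  out$distance <- geom_mat(out$distance, TRUE, 0)
  if (!is.null(out$labels)) {
    lab <- geom_mat(out$labels, TRUE, 0)
    storage.mode(lab) <- "integer"
    out$labels <- lab
  }
  if (!is.null(out$class_onehot)) {
    oh <- out$class_onehot
    oh[, , 1L] <- geom_mat(oh[, , 1L], TRUE, 1)
    for (c in 2:dim(oh)[3L]) oh[, , c] <- geom_mat(oh[, , c], TRUE, 0)
    out$class_onehot <- oh
  }
  if (do_c) img <- (img - 0.5) * c_fac + 0.5
  if (do_b) img <- img + b_sh
  out$image <- pmin(pmax(img, 0), 1)
  out
}
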