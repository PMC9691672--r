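# Instance reconstruction: size-adaptive smoothing of the predicted distance
# map, local-maxima seeding, marker-controlled watershed constrained to the
# thresholded foreground, refinement (tiny-object removal, hole filling),
# per-instance class voting, test-time augmentation and model ensembling.

#' Merge-stage configuration
#'
#' @param binary_threshold Threshold on the sigmoid foreground head
#'   (strictly between 0 and 1).
#' @param min_instance_area Instances smaller than this many pixels are
#'   removed during refinement (default 30).
#' @param sigma_scale Gaussian smoothing sigma as a fraction of the
#'   equivalent radius `sqrt(avg_area / pi)` of the mean nucleus.
#' @param min_seed_distance_scale Minimum seed separation as a fraction of
#'   the equivalent radius.
#' @param peak_floor Seeds must exceed this fraction of the smoothed map
#'   maximum.
#' @param fallback_area Mean-nucleus-area fallback when the thresholded
#'   foreground is empty.
#' @export
merge_config <- function(binary_threshold = 0.5, min_instance_area = 30L,
                         sigma_scale = 0.5, min_seed_distance_scale = 1.0,
                         peak_floor = 0.1, fallback_area = 100) {
  if (binary_threshold <= 0 || binary_threshold >= 1)
    stop("binary_threshold must be in (0, 1)")
  if (min_instance_area < 0) stop("min_instance_area must be >= 0")
  structure(list(binary_threshold = binary_threshold,
                 min_instance_area = as.integer(min_instance_area),
                 sigma_scale = sigma_scale,
                 min_seed_distance_scale = min_seed_distance_scale,
                 peak_floor = peak_floor, fallback_area = fallback_area),
            class = "merge_config")
}

#' Average nucleus area from the semantic segmentation output
#'
#' Thresholds the foreground probability map, labels 8-connected components
#' and returns their mean area. An empty foreground returns the configured
#' fallback area with `fallback = TRUE`.
#'
#' @param foreground_prob Probability map in `[0, 1]`.
#' @param threshold Binarization threshold.
#' @param fallback_area Area returned when no component exists.
#' @return List with `avg_area`, `n_components`, `fallback`.
#' @export
estimate_avg_nucleus_size <- function(foreground_prob, threshold = 0.5,
                                      fallback_area = 100) {
  if (any(foreground_prob < 0) || any(foreground_prob > 1))
    stop("foreground_prob must lie in [0, 1]")
  comp <- .label_components(foreground_prob > threshold, 8L)
  n <- max(comp)
  if (n == 0L)
    return(list(avg_area = fallback_area, n_components = 0L, fallback = TRUE))
  list(avg_area = mean(tabulate(comp[comp > 0L], nbins = n)),
       n_components = n, fallback = FALSE)
}

#' Smoothing sigma derived from the average nucleus area
#'
#' `sigma = sigma_scale * sqrt(avg_area / pi)`, i.e. proportional to the
#' equivalent radius of the mean nucleus.
#' @param avg_area Mean nucleus area in pixels.
#' @param sigma_scale Proportionality constant.
#' @export
smoothing_sigma <- function(avg_area, sigma_scale = 0.5) {
  if (avg_area <= 0) stop("avg_area must be positive")
  sigma_scale * sqrt(avg_area / pi)
}

# Separable Gaussian filter with reflective boundaries, kernel truncated at
# 4 sigma. Preserves constants exactly.
gaussian_filter_reflect <- function(x, sigma) {
  if (sigma <= 0) return(x)
  r <- max(1L, ceiling(4 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k <- k / sum(k)
  reflect_idx <- function(i, n) {
    # symmetric padding (1 2 3 | 3 2 1), valid for arbitrarily large
    # kernel radii via the period-2n mirror map
    m <- (i - 1L) %% (2L * n)
    m[m < 0L] <- m[m < 0L] + 2L * n
    over <- m >= n
    m[over] <- 2L * n - 1L - m[over]
    m + 1L
  }
  h <- nrow(x); w <- ncol(x)
  y <- matrix(0, h, w)
  for (o in -r:r)
    y <- y + k[o + r + 1L] * x[reflect_idx(seq_len(h) + o, h), , drop = FALSE]
  z <- matrix(0, h, w)
  for (o in -r:r)
    z <- z + k[o + r + 1L] * y[, reflect_idx(seq_len(w) + o, w), drop = FALSE]
  z
}

#' Smooth a predicted distance map
#'
#' Clamps negative predictions to zero, then applies a Gaussian filter whose
#' sigma is proportional to the equivalent radius of the mean nucleus
#' (see [smoothing_sigma()]), with reflective boundary handling.
#'
#' @param distance_pred Real-valued predicted distance map.
#' @param avg_area Mean nucleus area in pixels.
#' @param config A [merge_config()].
#' @export
smooth_distance <- function(distance_pred, avg_area, config = merge_config()) {
  if (avg_area <= 0) stop("avg_area must be positive")
  x <- pmax(distance_pred, 0)
  gaussian_filter_reflect(x, smoothing_sigma(avg_area, config$sigma_scale))
}

#' Detect watershed seeds as local maxima of the smoothed distance map
#'
#' Candidate pixels are strict neighborhood maxima (window of the minimum
#' seed separation) restricted to the foreground and above
#' `peak_floor * max(map)`. Candidates are then accepted greedily in order
#' of decreasing value (ties: lowest row, then column) subject to a minimum
#' pairwise Euclidean separation of `min_seed_distance_scale` equivalent
#' radii.
#'
#' @param smoothed Smoothed distance map.
#' @param foreground Binary foreground mask.
#' @param avg_area Mean nucleus area in pixels.
#' @param config A [merge_config()].
#' @return Integer seed label mask (0 = no seed; seeds numbered in
#'   acceptance order).
#' @export
find_seeds <- function(smoothed, foreground, avg_area,
                       config = merge_config()) {
  if (!identical(dim(smoothed), dim(foreground)))
    stop("smoothed and foreground must share one shape")
  h <- nrow(smoothed); w <- ncol(smoothed)
  seeds <- matrix(0L, h, w)
  mx <- max(smoothed)
  if (mx <= 0) return(seeds)
  r_eq <- sqrt(avg_area / pi)
  min_sep <- config$min_seed_distance_scale * r_eq
  win <- max(1L, ceiling(min_sep))
  # separable running maximum over a (2*win+1)^2 Chebyshev window
  pad_max_shift <- function(x, o, along_rows) {
    if (along_rows) {
      idx <- pmin(pmax(seq_len(h) + o, 1L), h)
      x[idx, , drop = FALSE]
    } else {
      idx <- pmin(pmax(seq_len(w) + o, 1L), w)
      x[, idx, drop = FALSE]
    }
  }
  rowmax <- smoothed
  for (o in setdiff(-win:win, 0L))
    rowmax <- pmax(rowmax, pad_max_shift(smoothed, o, TRUE))
  nbmax <- rowmax
  for (o in setdiff(-win:win, 0L))
    nbmax <- pmax(nbmax, pad_max_shift(rowmax, o, FALSE))
  cand <- which(smoothed == nbmax & foreground > 0 &
                smoothed > config$peak_floor * mx)
  if (!length(cand)) return(seeds)
  rows <- (cand - 1L) %% h + 1L
  cols <- (cand - 1L) %/% h + 1L
  ord <- order(-smoothed[cand], rows, cols)
  acc_r <- numeric(0); acc_c <- numeric(0)
  n <- 0L
  for (i in ord) {
    if (n > 0L &&
        any((acc_r - rows[i])^2 + (acc_c - cols[i])^2 < min_sep^2)) next
    n <- n + 1L
    acc_r <- c(acc_r, rows[i]); acc_c <- c(acc_c, cols[i])
    seeds[rows[i], cols[i]] <- n
  }
  seeds
}

#' Marker-controlled watershed on the negated smoothed distance map
#'
#' Floods the topographic surface `-smoothed` from the seed markers,
#' restricted to the foreground (4-connectivity, deterministic FIFO tie
#' breaking). Foreground components containing no seed each receive a single
#' fresh label, so no detected tissue is silently dropped. Output labels are
#' contiguous 1..N.
#'
#' @param smoothed Smoothed distance map.
#' @param seeds Integer seed label mask (see [find_seeds()]).
#' @param foreground Binary foreground mask; seeds must lie inside it.
#' @export
watershed_instances <- function(smoothed, seeds, foreground) {
  if (!identical(dim(smoothed), dim(seeds)) ||
      !identical(dim(smoothed), dim(foreground)))
    stop("smoothed, seeds and foreground must share one shape")
  fg <- foreground > 0
  if (any(seeds > 0L & !fg)) stop("seeds must lie inside the foreground")
  lab <- .ws_flood(-smoothed, seeds, fg)
  orphan <- fg & lab == 0L
  if (any(orphan)) {
    extra <- .label_components(orphan, 4L)
    lab[orphan] <- max(lab) + extra[orphan]
  }
  relabel_contiguous(lab)
}

relabel_contiguous <- function(labels) {
  v <- labels[labels > 0L]
  if (!length(v)) return(labels)
  ids <- sort(unique(as.integer(v)))
  if (identical(ids, seq_along(ids))) return(labels)
  map <- integer(max(ids))
  map[ids] <- seq_along(ids)
  labels[labels > 0L] <- map[labels[labels > 0L]]
  labels
}

#' Refine an instance label mask
#'
#' Removes instances with area below `min_instance_area`, absorbs background
#' regions fully enclosed by a single instance into it (hole filling), and
#' relabels contiguously. Idempotent.
#'
#' @param labels Instance label mask.
#' @param config A [merge_config()].
#' @export
refine_instances <- function(labels, config = merge_config()) {
  check_label_mask(labels)
  areas <- instance_areas(labels)
  kill <- which(areas < config$min_instance_area)
  if (length(kill)) labels[labels %in% kill] <- 0L
  labels <- relabel_contiguous(labels)
  # hole filling: background components not touching the border whose
  # 8-neighborhood carries exactly one instance label
  holes <- .label_components(labels == 0L, 4L)
  border_ids <- unique(c(holes[1L, ], holes[nrow(holes), ],
                         holes[, 1L], holes[, ncol(holes)]))
  h <- nrow(labels); w <- ncol(labels)
  for (hid in setdiff(unique(holes[holes > 0L]), border_ids)) {
    hm <- holes == hid
    bb <- mask_bbox(hm)
    sub <- hm[bb$rows, bb$cols, drop = FALSE]
    lsub <- labels[bb$rows, bb$cols, drop = FALSE]
    nb <- integer(0)
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0L && dc == 0L) next
      rs <- pmin(pmax(which(sub, arr.ind = TRUE)[, 1L] + dr, 1L), nrow(sub))
      cs <- pmin(pmax(which(sub, arr.ind = TRUE)[, 2L] + dc, 1L), ncol(sub))
      nb <- c(nb, lsub[cbind(rs, cs)])
    }
    nb <- setdiff(unique(nb), 0L)
    if (length(nb) == 1L) {
      tmp <- labels[bb$rows, bb$cols, drop = FALSE]
      tmp[sub] <- nb
      labels[bb$rows, bb$cols] <- tmp
    }
  }
  labels
}

#' Assign a class to each instance by pixel majority vote
#'
#' Inside each detected instance the per-pixel class is the argmax over the
#' K nucleus channels of the classifier output (background channel
#' excluded); the instance class is the modal pixel class, ties broken
#' toward the lowest class index.
#'
#' @param instances Instance label mask.
#' @param class_probs H x W x (K+1) softmax output (channel 1 = background).
#' @return List with `table` (data frame: instance, class, vote_fraction)
#'   and `class_mask` (integer matrix).
#' @export
assign_classes <- function(instances, class_probs) {
  check_label_mask(instances)
  d <- dim(class_probs)
  if (!identical(dim(instances), d[1:2]))
    stop("instances and class_probs must share one spatial shape")
  k <- d[3L] - 1L
  n_pix <- prod(d[1:2])
  pm <- matrix(class_probs, n_pix, d[3L])[, -1L, drop = FALSE]
  pix_class <- max.col(pm, ties.method = "first")
  ids <- label_ids(instances)
  class_mask <- matrix(0L, d[1L], d[2L])
  rows <- lapply(ids, function(i) {
    sel <- which(instances == i)
    votes <- tabulate(pix_class[sel], nbins = k)
    cl <- which.max(votes) # ties -> lowest index
    class_mask[sel] <<- cl
    data.frame(instance = i, class = cl,
               vote_fraction = votes[cl] / length(sel))
  })
  list(table = if (length(rows)) do.call(rbind, rows) else
         data.frame(instance = integer(0), class = integer(0),
                    vote_fraction = numeric(0)),
       class_mask = class_mask)
}

#' Predict with test-time augmentation
#'
#' When `tta` is on, the network is run on the identity, the 90-degree
#' rotated and the horizontally flipped image; each output is mapped back
#' through the inverse transform and the three maps are averaged elementwise
#' (distances as reals, probabilities in probability space).
#'
#' @param model A `nucseg_net`.
#' @param image H x W x 3 input with sides divisible by the network stride.
#' @param tta Apply the 3-member augmentation set?
#' @export
predict_with_tta <- function(model, image, tta = FALSE) {
  stopifnot(inherits(model, "nucseg_net"))
  if (!tta) return(net_forward(model, image))
  outs <- list(
    net_forward(model, image),
    lapply(net_forward(model, rot90_ccw(image)), rot90_cw),
    lapply(net_forward(model, flip_horizontal(image)), flip_horizontal))
  avg <- outs[[1L]]
  for (nm in names(avg))
    avg[[nm]] <- (outs[[1L]][[nm]] + outs[[2L]][[nm]] + outs[[3L]][[nm]]) / 3
  avg
}

#' Average the predictions of an ensemble of models
#'
#' Elementwise mean of each model's (optionally TTA-averaged) output maps,
#' e.g. the five fold models of a cross-validation run.
#'
#' @param models Non-empty list of `nucseg_net` objects sharing one
#'   architecture configuration.
#' @inheritParams predict_with_tta
#' @export
ensemble_predict <- function(models, image, tta = FALSE) {
  if (!length(models)) stop("ensemble requires at least one model")
  cfgs <- lapply(models, function(m) unclass(m$config))
  if (!all(vapply(cfgs, identical, TRUE, cfgs[[1L]])))
    stop("all ensemble members must share one architecture configuration")
  outs <- lapply(models, predict_with_tta, image = image, tta = tta)
  avg <- outs[[1L]]
  if (length(outs) > 1L)
    for (nm in names(avg)) {
      for (i in 2:length(outs)) avg[[nm]] <- avg[[nm]] + outs[[i]][[nm]]
      avg[[nm]] <- avg[[nm]] / length(outs)
    }
  avg
}

#' Pad and resize an image to a network-valid size, and invert it
#'
#' `pad_to_valid` pads with white (1.0) on the right/bottom to a square of
#' side `max(H, W)`, then resizes to the nearest multiple of 32 (ties round
#' up). `unpad_labels` inverts both steps on a predicted label mask using
#' nearest-neighbor resampling.
#'
#' @param image H x W x 3 image in `[0, 1]`.
#' @return For `pad_to_valid`, a list with `image` and `record` (a pad
#'   record holding the original size, padded side and resized side).
#' @export
pad_to_valid <- function(image) {
  d <- dim(image)
  if (length(d) != 3L || d[1L] < 1L || d[2L] < 1L) stop("image must be H x W x C")
  side <- max(d[1:2])
  sq <- array(1, c(side, side, d[3L]))
  sq[seq_len(d[1L]), seq_len(d[2L]), ] <- image
  resized_side <- max(32L, as.integer(32L * floor(side / 32 + 0.5)))
  out <- if (resized_side == side) sq else {
    r <- array(0, c(resized_side, resized_side, d[3L]))
    for (ch in seq_len(d[3L]))
      r[, , ch] <- as.matrix(EBImage::resize(sq[, , ch], w = resized_side,
                                             h = resized_side,
                                             filter = "bilinear"))
    r
  }
  list(image = out,
       record = structure(list(original_height = d[1L], original_width = d[2L],
                               padded_side = side,
                               resized_side = resized_side, pad_value = 1),
                          class = "nucseg_pad_record"))
}

#' @rdname pad_to_valid
#' @param labels Label mask at the resized scale.
#' @param record Pad record returned by `pad_to_valid`.
#' @param relabel Relabel instances contiguously after cropping (disable for
#'   class-code masks, whose values are categories rather than instance
#'   ids).
#' @export
unpad_labels <- function(labels, record, relabel = TRUE) {
  stopifnot(inherits(record, "nucseg_pad_record"))
  side <- record$padded_side
  back <- if (record$resized_side == side) labels else
    as.matrix(EBImage::resize(labels, w = side, h = side, filter = "none"))
  out <- back[seq_len(record$original_height), seq_len(record$original_width),
              drop = FALSE]
  storage.mode(out) <- "integer"
  if (relabel) relabel_contiguous(out) else out
}

#' Reconstruct instances from network output maps
#'
#' The full merge: threshold the foreground probabilities, estimate the mean
#' nucleus size, smooth the distance prediction, seed at its local maxima,
#' run the marker-controlled watershed and refine the result. Deterministic.
#'
#' @param distance_pred Predicted distance map.
#' @param foreground_prob Predicted foreground probability map.
#' @param config A [merge_config()].
#' @return Instance label mask.
#' @export
merge_outputs <- function(distance_pred, foreground_prob,
                          config = merge_config()) {
  est <- estimate_avg_nucleus_size(foreground_prob, config$binary_threshold,
                                   config$fallback_area)
  fg <- (foreground_prob > config$binary_threshold) * 1
  sm <- smooth_distance(distance_pred, est$avg_area, config)
  seeds <- find_seeds(sm, fg, est$avg_area, config)
  lab <- watershed_instances(sm, seeds, fg)
  refine_instances(lab, config)
}
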