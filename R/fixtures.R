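#' Configuration for synthetic H&E-like fixtures
#'
#' Describes a synthetic histology patch: clusters of rotated elliptical
#' nuclei rendered as dark purple objects with smooth radial falloff over a
#' pink background, with additive Gaussian pixel noise — the contrast
#' structure of a hematoxylin & eosin stain without modeling stain physics.
#' Instance labels are draw order; where overlaps are allowed, the
#' later-drawn nucleus wins contested pixels so the label mask is always a
#' partition.
#'
#' @param height,width Patch size in pixels; each must be at least 64 and
#'   divisible by 32 so patches feed the default network directly.
#' @param n_nuclei Number of nuclei to attempt to place (placement retries
#'   may drop some; at least one is always placed).
#' @param radius_range Min/max semi-major axis in pixels (min must be >= 2).
#' @param eccentricity_range Min/max eccentricity in `[0, 1)`; the
#'   semi-minor axis is `a * sqrt(1 - e^2)`.
#' @param overlap_allowed May nuclei overlap?
#' @param max_overlap_fraction When overlapping, the maximum allowed pairwise
#'   pixel overlap as a fraction of the smaller ellipse, in `[0, 1)`.
#' @param min_spacing Minimum Euclidean distance between nucleus centers in
#'   pixels (0 disables the constraint).
#' @param n_classes Number of nucleus classes (0 = unclassified).
#' @param class_proportions Simplex weights over classes (defaults to equal);
#'   must sum to 1.
#' @param noise_sd Standard deviation of the additive Gaussian intensity
#'   noise, in `[0, 1]` intensity units.
#' @param seed Integer seed; identical config and seed give bit-identical
#'   output.
#' @return An object of class `fixture_config`.
#' @export
fixture_config <- function(height = 256L, width = 256L, n_nuclei = 30L,
                           radius_range = c(8, 14),
                           eccentricity_range = c(0, 0.6),
                           overlap_allowed = FALSE,
                           max_overlap_fraction = 0.2,
                           min_spacing = 0,
                           n_classes = 0L, class_proportions = NULL,
                           noise_sd = 0.03, seed = 1L) {
  height <- as.integer(height); width <- as.integer(width)
  if (height < 64L || width < 64L || height %% 32L != 0L || width %% 32L != 0L)
    stop("height and width must each be >= 64 and divisible by 32")
  n_nuclei <- as.integer(n_nuclei)
  if (n_nuclei < 1L) stop("n_nuclei must be >= 1")
  if (length(radius_range) != 2L || radius_range[1L] < 2 ||
      diff(radius_range) < 0)
    stop("radius_range must be (min, max) with min >= 2")
  if (eccentricity_range[1L] < 0 || eccentricity_range[2L] >= 1 ||
      diff(eccentricity_range) < 0)
    stop("eccentricity_range must lie in [0, 1)")
  if (max_overlap_fraction < 0 || max_overlap_fraction >= 1)
    stop("max_overlap_fraction must be in [0, 1)")
  n_classes <- as.integer(n_classes)
  if (n_classes > 0L) {
    if (is.null(class_proportions))
      class_proportions <- rep(1 / n_classes, n_classes)
    if (length(class_proportions) != n_classes ||
        abs(sum(class_proportions) - 1) > 1e-8 || any(class_proportions < 0))
      stop("class_proportions must be non-negative and sum to 1")
  } else class_proportions <- NULL
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  min_area <- pi * radius_range[1L]^2 * sqrt(1 - eccentricity_range[2L]^2)
  if (n_nuclei * min_area > 0.9 * height * width)
    stop(sprintf(
      "impossible geometry: %d nuclei of minimum area %.0f px exceed 90%% of the %d x %d canvas",
      n_nuclei, min_area, height, width))
  structure(list(height = height, width = width, n_nuclei = n_nuclei,
                 radius_range = radius_range,
                 eccentricity_range = eccentricity_range,
                 overlap_allowed = isTRUE(overlap_allowed),
                 max_overlap_fraction = max_overlap_fraction,
                 min_spacing = min_spacing,
                 n_classes = n_classes,
                 class_proportions = class_proportions,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "fixture_config")
}

# Pixel set of a rotated ellipse; returns linear indices plus the radial
# coordinate q = 1 - (u^2 + v^2) in [0, 1] (1 at the center).
ellipse_pixels <- function(crow, ccol, a, b, theta, height, width) {
  r0 <- max(1L, floor(crow - a)); r1 <- min(height, ceiling(crow + a))
  c0 <- max(1L, floor(ccol - a)); c1 <- min(width, ceiling(ccol + a))
  rows <- r0:r1; cols <- c0:c1
  dr <- rows - crow
  dc <- cols - ccol
  ct <- cos(theta); st <- sin(theta)
  u <- (outer(dr, dc, function(x, y) x * ct + y * st)) / a
  v <- (outer(dr, dc, function(x, y) -x * st + y * ct)) / b
  q <- 1 - (u^2 + v^2)
  # tolerance keeps exact-boundary pixels (e.g. x^2 + y^2 = r^2) that
  # rotation arithmetic would otherwise lose to roundoff
  keep <- which(q >= -1e-9)
  q[q < 0] <- 0
  idx <- as.vector(outer(rows, (cols - 1L) * height, `+`))[keep]
  list(idx = idx, q = q[keep])
}

# Nucleus / background colors; classes get slight tints so appearance carries
# a (weak) class signal.
fixture_palette <- function(n_classes) {
  bg <- c(0.93, 0.76, 0.85)
  base <- c(0.38, 0.22, 0.52)
  tints <- list(c(0, 0, 0), c(0.08, -0.04, 0.02), c(-0.06, 0.05, -0.05),
                c(0.03, 0.08, 0.06), c(-0.04, -0.06, 0.08))
  nuc <- if (n_classes > 0L)
    lapply(seq_len(n_classes), function(k)
      pmin(pmax(base + tints[[(k - 1L) %% length(tints) + 1L]], 0), 1))
  else list(base)
  list(bg = bg, nuc = nuc)
}

#' Generate one synthetic nuclei image with ground truth
#'
#' Places up to `n_nuclei` rotated ellipses subject to the overlap and
#' spacing constraints of the config (later-drawn nuclei win contested
#' pixels; a placement that would disconnect or erase an earlier nucleus is
#' retried), renders them over a pink background with radial intensity
#' falloff and additive Gaussian noise, and returns the image with its
#' instance label mask and, when `n_classes > 0`, a per-pixel class mask
#' constant within each instance.
#'
#' @param config A [fixture_config()].
#' @return A list with `image` (H x W x 3 in `[0, 1]`), `labels` (integer
#'   instance mask, 0 = background, labels contiguous 1..N), `classes`
#'   (integer class mask or `NULL`) and `meta` (one row per instance:
#'   class, center, axes, orientation, area).
#' @export
generate_nuclei_image <- function(config) {
  stopifnot(inherits(config, "fixture_config"))
  h <- config$height; w <- config$width
  with_seed(config$seed, {
    labels <- matrix(0L, h, w)
    pix <- list(); qs <- list()
    meta <- list()
    centers <- matrix(0, 0, 2)
    orig_area <- integer(0)
    k <- 0L
    for (try_k in seq_len(config$n_nuclei)) {
      placed <- FALSE
      for (attempt in 1:60) {
        a <- stats::runif(1, config$radius_range[1L], config$radius_range[2L])
        e <- stats::runif(1, config$eccentricity_range[1L],
                          config$eccentricity_range[2L])
        b <- a * sqrt(1 - e^2)
        theta <- stats::runif(1, 0, pi)
        # integer pixel centers keep discrete geometry exact (a circle of
        # radius r covers the discrete disk {x^2 + y^2 <= r^2})
        crow <- round(stats::runif(1, a + 1, h - a))
        ccol <- round(stats::runif(1, a + 1, w - a))
        if (nrow(centers) > 0 && config$min_spacing > 0) {
          d2 <- (centers[, 1L] - crow)^2 + (centers[, 2L] - ccol)^2
          if (any(d2 < config$min_spacing^2)) next
        }
        ep <- ellipse_pixels(crow, ccol, a, b, theta, h, w)
        hit <- labels[ep$idx]
        if (any(hit > 0L)) {
          if (!config$overlap_allowed) next
          ov <- table(hit[hit > 0L])
          frac <- as.numeric(ov) /
            pmin(length(ep$idx), orig_area[as.integer(names(ov))])
          if (any(frac > config$max_overlap_fraction)) next
          # earlier instances must survive connected after losing pixels
          broken <- FALSE
          for (j in as.integer(names(ov))) {
            owned <- pix[[j]][labels[pix[[j]]] == j]
            rem <- setdiff(owned, ep$idx)
            if (!length(rem)) { broken <- TRUE; break }
            mj <- matrix(FALSE, h, w); mj[rem] <- TRUE
            bb <- mask_bbox(mj)
            comp <- .label_components(mj[bb$rows, bb$cols, drop = FALSE], 4L)
            if (max(comp) > 1L) { broken <- TRUE; break }
          }
          if (broken) next
        }
        k <- k + 1L
        labels[ep$idx] <- k
        pix[[k]] <- ep$idx; qs[[k]] <- ep$q
        centers <- rbind(centers, c(crow, ccol))
        orig_area <- c(orig_area, length(ep$idx))
        cls <- if (config$n_classes > 0L)
          sample.int(config$n_classes, 1L, prob = config$class_proportions)
        else NA_integer_
        meta[[k]] <- data.frame(instance = k, class = cls,
                                center_row = crow, center_col = ccol,
                                radius_major = a, radius_minor = b,
                                theta = theta, area = length(ep$idx))
        placed <- TRUE
        break
      }
    }
    meta <- do.call(rbind, meta)
    meta$area <- instance_areas(labels)

    pal <- fixture_palette(config$n_classes)
    image <- array(rep(pal$bg, each = h * w), c(h, w, 3L))
    for (j in seq_len(k)) {
      col_j <- if (config$n_classes > 0L) pal$nuc[[meta$class[j]]] else pal$nuc[[1L]]
      own <- labels[pix[[j]]] == j
      idx <- pix[[j]][own]; q <- qs[[j]][own]
      mixv <- 0.55 + 0.45 * q
      for (ch in 1:3)
        image[idx + (ch - 1L) * h * w] <-
          pal$bg[ch] + (col_j[ch] - pal$bg[ch]) * mixv
    }
    if (config$noise_sd > 0)
      image <- image + stats::rnorm(length(image), 0, config$noise_sd)
    image <- pmin(pmax(image, 0), 1)

    classes <- NULL
    if (config$n_classes > 0L) {
      classes <- matrix(0L, h, w)
      for (j in seq_len(k)) classes[labels == j] <- meta$class[j]
    }
    list(image = image, labels = labels, classes = classes, meta = meta)
  })
}

#' Generate a dataset of synthetic samples
#'
#' Draws `n_samples` fixtures with per-sample seeds `seed + i`. When `dir` is
#' given, images are written as 8-bit RGB PNG, instance masks as 16-bit
#' single-channel TIFF, class masks as 8-bit PNG, and a `manifest.csv` with
#' columns image_path, mask_path, class_path, n_instances, seed.
#'
#' @param n_samples Number of samples (>= 1).
#' @param config A [fixture_config()]; its own `seed` is ignored in favor of
#'   the derived per-sample seeds.
#' @param seed Base seed.
#' @param dir Optional output directory (created if missing).
#' @return List with `samples` (list of [generate_nuclei_image()] results)
#'   and `manifest` (data frame).
#' @export
generate_dataset <- function(n_samples, config, seed = 1L, dir = NULL) {
  stopifnot(inherits(config, "fixture_config"))
  n_samples <- as.integer(n_samples)
  if (n_samples < 1L) stop("n_samples must be >= 1")
  write_out <- !is.null(dir)
  if (write_out) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    if (!dir.exists(dir)) stop(sprintf("cannot create output directory '%s'", dir))
  }
  samples <- vector("list", n_samples)
  rows <- vector("list", n_samples)
  for (i in seq_len(n_samples)) {
    cfg <- config
    cfg$seed <- as.integer(seed + i)
    s <- generate_nuclei_image(cfg)
    samples[[i]] <- s
    ip <- mp <- cp <- NA_character_
    if (write_out) {
      ip <- file.path(dir, sprintf("sample%03d_image.png", i))
      mp <- file.path(dir, sprintf("sample%03d_mask.tiff", i))
      write_image_png(s$image, ip)
      write_label_mask(s$labels, mp)
      if (!is.null(s$classes)) {
        cp <- file.path(dir, sprintf("sample%03d_classes.png", i))
        write_class_mask(s$classes, cp)
      }
    }
    rows[[i]] <- data.frame(sample_id = i, image_path = ip, mask_path = mp,
                            class_path = cp,
                            n_instances = length(label_ids(s$labels)),
                            seed = cfg$seed, stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  if (write_out)
    utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                     row.names = FALSE)
  list(samples = samples, manifest = manifest)
}
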