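# Shared internal helpers.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Discrete disk structuring element: pixels with x^2 + y^2 <= r^2.
# At r = 1 this is the 4-neighbour cross (unlike EBImage::makeBrush, whose
# size-3 "disc" is a full box).
disk_brush <- function(r) {
  r <- as.integer(r)
  stopifnot(r >= 0L)
  g <- expand.grid(x = -r:r, y = -r:r)
  matrix(as.numeric(g$x^2 + g$y^2 <= r^2), 2L * r + 1L, 2L * r + 1L)
}

# 90-degree rotations of H x W matrices or H x W x C arrays.
# rot90_ccw maps (i, j) in H x W to (W + 1 - j, i) in W x H.
rot90_ccw <- function(x) {
  if (length(dim(x)) == 2L) t(x)[rev(seq_len(ncol(x))), , drop = FALSE]
  else {
    out <- array(0, c(dim(x)[2L], dim(x)[1L], dim(x)[3L]))
    for (c in seq_len(dim(x)[3L])) out[, , c] <- rot90_ccw(x[, , c])
    out
  }
}

rot90_cw <- function(x) {
  if (length(dim(x)) == 2L) t(x)[, rev(seq_len(nrow(x))), drop = FALSE]
  else {
    out <- array(0, c(dim(x)[2L], dim(x)[1L], dim(x)[3L]))
    for (c in seq_len(dim(x)[3L])) out[, , c] <- rot90_cw(x[, , c])
    out
  }
}

flip_horizontal <- function(x) {
  if (length(dim(x)) == 2L) x[, rev(seq_len(ncol(x))), drop = FALSE]
  else x[, rev(seq_len(dim(x)[2L])), , drop = FALSE]
}

flip_vertical <- function(x) {
  if (length(dim(x)) == 2L) x[rev(seq_len(nrow(x))), , drop = FALSE]
  else x[rev(seq_len(dim(x)[1L])), , , drop = FALSE]
}

# Validate an instance label mask: non-negative integers, labels 1..N with
# no gaps.
check_label_mask <- function(labels, arg = "labels") {
  if (!is.matrix(labels)) stop(sprintf("%s must be a matrix", arg))
  v <- labels[labels > 0]
  if (any(labels < 0) || any(labels != round(labels)))
    stop(sprintf("%s must contain non-negative integers", arg))
  if (length(v)) {
    ids <- sort(unique(as.integer(v)))
    if (!identical(ids, seq_len(max(ids))))
      stop(sprintf("%s labels must be contiguous 1..N", arg))
  }
  invisible(labels)
}

label_ids <- function(labels) {
  v <- labels[labels > 0]
  if (!length(v)) integer(0) else seq_len(max(v))
}

instance_areas <- function(labels) {
  v <- as.integer(labels[labels > 0])
  if (!length(v)) return(integer(0))
  tabulate(v, nbins = max(v))
}

# Bounding box of a logical mask with `pad` pixels of margin, clipped to the
# image; returns row/col index vectors.
mask_bbox <- function(mask, pad = 1L) {
  w <- which(mask, arr.ind = TRUE)
  r0 <- max(1L, min(w[, 1L]) - pad); r1 <- min(nrow(mask), max(w[, 1L]) + pad)
  c0 <- max(1L, min(w[, 2L]) - pad); c1 <- min(ncol(mask), max(w[, 2L]) + pad)
  list(rows = r0:r1, cols = c0:c1)
}
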