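# Shared fixtures built in code.

# Discrete disk instance centered at (cr, cc): pixels with dx^2 + dy^2 <= r^2.
disk_mask <- function(h, w, cr, cc, r, label = 1L) {
  m <- matrix(0L, h, w)
  for (i in seq_len(h)) for (j in seq_len(w))
    if ((i - cr)^2 + (j - cc)^2 <= r^2) m[i, j] <- label
  m
}

# Axis-aligned square instance.
square_mask <- function(h, w, r0, c0, side, label = 1L, base = NULL) {
  m <- if (is.null(base)) matrix(0L, h, w) else base
  m[r0:(r0 + side - 1L), c0:(c0 + side - 1L)] <- label
  m
}

# Small fixture config used across tests.
tiny_fixture <- function(seed = 1L, ...) {
  fixture_config(height = 96L, width = 96L, n_nuclei = 6L,
                 radius_range = c(5, 8), eccentricity_range = c(0, 0.4),
                 noise_sd = 0.02, seed = seed, ...)
}

# Tiny network config for CPU-fast tests.
tiny_net_config <- function(...)
  network_config(depth = 2L, base_filters = 4L, dropout_rate = 0,
                 n_classes = 2L, ...)

# A network whose output maps are constant: zero weights, chosen head biases.
constant_dual_net <- function(distance = 0.3, fg_prob = 0.2) {
  net <- build_dual_decoder(tiny_net_config(), seed = 1L)
  net$params <- lapply(net$params, function(p) p * 0)
  net$params$dist_head_b[] <- distance
  net$params$bin_head_b[] <- stats::qlogis(fg_prob)
  net
}

# Random instance mask: a few non-touching rectangles; used for metric
# property tests.
random_rect_mask <- function(h, w, n, seed) {
  set.seed(seed)
  m <- matrix(0L, h, w)
  k <- 0L
  for (i in seq_len(n)) {
    for (attempt in 1:30) {
      sh <- sample(2:6, 1L); sw <- sample(2:6, 1L)
      r0 <- sample(h - sh, 1L); c0 <- sample(w - sw, 1L)
      rr <- r0:(r0 + sh); cc <- c0:(c0 + sw)
      rpad <- max(1L, r0 - 1L):min(h, r0 + sh + 1L)
      cpad <- max(1L, c0 - 1L):min(w, c0 + sw + 1L)
      if (all(m[rpad, cpad] == 0L)) {
        k <- k + 1L
        m[rr, cc] <- k
        break
      }
    }
  }
  m
}

# Perturb an instance mask into a plausible prediction: shift some
# instances, drop others, add spurious ones.
perturb_mask <- function(gt, seed) {
  set.seed(seed)
  h <- nrow(gt); w <- ncol(gt)
  out <- matrix(0L, h, w)
  k <- 0L
  for (id in seq_len(max(gt, 0L))) {
    if (stats::runif(1) < 0.15) next # dropped instance
    sel <- which(gt == id, arr.ind = TRUE)
    dr <- sample(-1:1, 1L); dc <- sample(-1:1, 1L)
    rr <- pmin(pmax(sel[, 1L] + dr, 1L), h)
    cc <- pmin(pmax(sel[, 2L] + dc, 1L), w)
    k <- k + 1L
    out[cbind(rr, cc)] <- k
  }
  if (stats::runif(1) < 0.5) { # spurious blob in a free corner
    free <- which(out == 0L & gt == 0L, arr.ind = TRUE)
    if (nrow(free) > 8L) {
      p <- free[sample(nrow(free), 1L), ]
      rr <- p[1L]:min(h, p[1L] + 1L); cc <- p[2L]:min(w, p[2L] + 1L)
      if (all(out[rr, cc] == 0L)) out[rr, cc] <- k + 1L
    }
  }
  nucseg:::relabel_contiguous(out)
}
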