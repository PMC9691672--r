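test_that("intensity normalization maps integer ranges onto [0, 1]", {
  img <- array(255L, c(4, 4, 3))
  expect_equal(normalize_intensity(img), array(1, c(4, 4, 3)))
  expect_equal(normalize_intensity(array(0L, c(4, 4, 3))), array(0, c(4, 4, 3)))
  expect_equal(normalize_intensity(51L), 0.2)
  expect_error(normalize_intensity(array(300L, c(2, 2, 3))), "\\[0, 255\\]")
  expect_error(normalize_intensity(1L, max_value = 0), "positive")
})

test_that("refine_binary_mask separates touching instances", {
  # two 5x5 squares sharing a vertical border
  m <- square_mask(12, 16, 3, 3, 5, 1L)
  m <- square_mask(12, 16, 3, 8, 5, 2L, base = m)
  out <- refine_binary_mask(m)
  expect_true(all(out[m == 0L] == 0))
  comp <- nucseg:::.label_components(out > 0, 8L)
  expect_gte(max(comp), 2L)
  # components from different source instances are separated by >= 1 px gap
  expect_true(all(out[, 7:9] == 0) || {
    # at minimum, no output pixel of instance 1 is 8-adjacent to one of 2
    o1 <- which(out > 0 & m == 1L, arr.ind = TRUE)
    o2 <- which(out > 0 & m == 2L, arr.ind = TRUE)
    all(outer(o1[, 1], o2[, 1], function(a, b) abs(a - b)) > 1 |
        outer(o1[, 2], o2[, 2], function(a, b) abs(a - b)) > 1)
  })
})

test_that("erosion of a discrete disk matches the brute-force oracle", {
  m <- disk_mask(31, 31, 16, 16, 5)
  expect_equal(sum(m), 81L)
  out <- refine_binary_mask(m, erosion_radius = 1L)
  # oracle: keep pixel iff the whole radius-1 disk (4-neighbour cross) fits
  oracle <- matrix(0, 31, 31)
  for (i in 2:30) for (j in 2:30)
    if (m[i, j] && m[i - 1, j] && m[i + 1, j] && m[i, j - 1] && m[i, j + 1])
      oracle[i, j] <- 1
  expect_equal(out, oracle)
  expect_equal(sum(out), 53)
})

test_that("refinement handles empty masks and vanishing instances", {
  empty <- matrix(0L, 8, 8)
  expect_equal(refine_binary_mask(empty), matrix(0, 8, 8))
  single <- matrix(0L, 8, 8); single[4, 4] <- 1L
  expect_warning(out <- refine_binary_mask(single), "vanished")
  expect_equal(sum(out), 0)
})

test_that("border removal is idempotent", {
  for (seed in 1:5) {
    s <- generate_nuclei_image(tiny_fixture(seed = seed,
                                            overlap_allowed = TRUE,
                                            max_overlap_fraction = 0.3))
    once <- s$labels
    once[nucseg:::touching_border_pixels(s$labels)] <- 0L
    twice <- once
    twice[nucseg:::touching_border_pixels(once)] <- 0L
    expect_identical(once, twice)
  }
})

test_that("refined masks never leave distinct instances 8-connected", {
  for (seed in 1:10) {
    s <- generate_nuclei_image(tiny_fixture(
      seed = 300 + seed, overlap_allowed = TRUE, max_overlap_fraction = 0.4))
    out <- suppressWarnings(refine_binary_mask(s$labels))
    comp <- nucseg:::.label_components(out > 0, 8L)
    for (k in seq_len(max(comp))) {
      src <- unique(s$labels[comp == k])
      expect_length(src, 1L)
    }
  }
})

test_that("distance maps match the hand-computed 3x3 square", {
  m <- matrix(0L, 7, 7); m[3:5, 3:5] <- 1L
  d <- make_distance_map(m)
  expect_equal(d[4, 4], 1)
  border <- which(m == 1L & d < 1)
  expect_length(border, 8L)
  expect_true(all(d[border] == 0.5))
  expect_true(all(d[m == 0L] == 0))
})

test_that("distance map degenerate and vacuous cases", {
  expect_equal(make_distance_map(matrix(0L, 5, 5)), matrix(0, 5, 5))
  single <- matrix(0L, 5, 5); single[3, 3] <- 1L
  d <- make_distance_map(single)
  expect_equal(d[3, 3], 1)
  expect_equal(sum(d > 0), 1L)
})

test_that("thresholding the distance map reproduces the exact foreground", {
  for (seed in 1:5) {
    s <- generate_nuclei_image(tiny_fixture(seed = 40 + seed))
    d <- make_distance_map(s$labels)
    expect_identical(d > 0, s$labels > 0L)
    expect_true(all(d >= 0 & d <= 1))
    # every instance attains the maximum 1
    for (k in seq_len(max(s$labels)))
      expect_equal(max(d[s$labels == k]), 1)
  }
})

test_that("one-hot class masks are one-hot with correct channels", {
  m <- square_mask(10, 10, 2, 2, 3, 1L)
  cls <- matrix(0L, 10, 10); cls[m == 1L] <- 3L
  oh <- make_class_onehot(m, cls, n_classes = 4L)
  expect_equal(dim(oh), c(10L, 10L, 5L))
  expect_true(all(apply(oh, c(1, 2), sum) == 1))
  expect_true(all(oh[, , 4][m == 1L] == 1)) # channel 3 + 1
  # all-background input
  oh0 <- make_class_onehot(matrix(0L, 4, 4), matrix(0L, 4, 4), 2L)
  expect_true(all(oh0[, , 1] == 1) && all(oh0[, , -1] == 0))
  # mixed codes within an instance are rejected, naming the instance
  bad <- cls; bad[2, 2] <- 1L
  expect_error(make_class_onehot(m, bad, 4L), "instance 1")
})

test_that("augmentation with zero probabilities is the identity", {
  s <- generate_nuclei_image(tiny_fixture(seed = 3))
  sm <- prepare_sample(s$image, s$labels)
  p0 <- augment_config(prob_hflip = 0, prob_vflip = 0, prob_scale = 0,
                       prob_contrast = 0, prob_brightness = 0)
  out <- augment_sample(sm, p0, seed = 1)
  expect_identical(out$image, sm$image)
  expect_identical(out$refined_binary, sm$refined_binary)
  expect_identical(out$distance, sm$distance)
})

test_that("a forced horizontal flip is an involution and maps centroids", {
  s <- generate_nuclei_image(tiny_fixture(seed = 6))
  sm <- prepare_sample(s$image, s$labels)
  pf <- augment_config(prob_hflip = 1, prob_vflip = 0, prob_scale = 0,
                       prob_contrast = 0, prob_brightness = 0)
  once <- augment_sample(sm, pf, seed = 2)
  twice <- augment_sample(once, pf, seed = 2)
  expect_equal(twice$image, sm$image)
  expect_identical(twice$labels, sm$labels)
  # centroid columns map to W + 1 - col (1-based)
  w <- ncol(s$labels)
  for (k in seq_len(max(s$labels))) {
    c0 <- mean(which(s$labels == k, arr.ind = TRUE)[, 2])
    c1 <- mean(which(once$labels == k, arr.ind = TRUE)[, 2])
    expect_equal(c1, w + 1 - c0)
  }
})

test_that("flip-only augmentation commutes with target construction", {
  s <- generate_nuclei_image(tiny_fixture(seed = 8))
  sm <- prepare_sample(s$image, s$labels)
  pf <- augment_config(prob_hflip = 1, prob_vflip = 1, prob_scale = 0,
                       prob_contrast = 0, prob_brightness = 0)
  aug <- augment_sample(sm, pf, seed = 5)
  # flip the labels first, then rebuild the targets from them
  flipped_labels <- s$labels[rev(seq_len(nrow(s$labels))),
                             rev(seq_len(ncol(s$labels)))]
  expect_identical(aug$distance, make_distance_map(flipped_labels))
  expect_identical(aug$refined_binary,
                   suppressWarnings(refine_binary_mask(flipped_labels)))
})

test_that("augmentation scaling validates its range and stays in bounds", {
  s <- generate_nuclei_image(tiny_fixture(seed = 12))
  sm <- prepare_sample(s$image, s$labels)
  expect_error(augment_config(scale_range = c(-1, 1)), "positive")
  ps <- augment_config(prob_hflip = 0, prob_vflip = 0, prob_scale = 1,
                       scale_range = c(0.8, 0.8), prob_contrast = 0,
                       prob_brightness = 0)
  out <- augment_sample(sm, ps, seed = 3)
  expect_identical(dim(out$image), dim(sm$image))
  expect_true(all(out$refined_binary %in% c(0, 1)))
  expect_true(all(out$distance >= 0 & out$distance <= 1))
})
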