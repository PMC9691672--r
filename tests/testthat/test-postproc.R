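test_that("average nucleus size is the mean component area with fallback", {
  p <- matrix(0, 40, 40)
  p[2:9, 2:6] <- 1    # area 40
  p[20:29, 20:25] <- 1 # area 60
  est <- estimate_avg_nucleus_size(p, threshold = 0.5)
  expect_equal(est$avg_area, 50)
  expect_equal(est$n_components, 2L)
  expect_false(est$fallback)
  one <- matrix(0, 31, 31); one[disk_mask(31, 31, 16, 16, 5) == 1L] <- 1
  expect_equal(estimate_avg_nucleus_size(one)$avg_area, 81)
  empty <- estimate_avg_nucleus_size(matrix(0, 10, 10))
  expect_equal(empty$avg_area, 100)
  expect_true(empty$fallback)
  expect_error(estimate_avg_nucleus_size(matrix(2, 4, 4)), "\\[0, 1\\]")
})

test_that("smoothing sigma follows the equivalent-radius rule", {
  expect_equal(smoothing_sigma(100, 0.5), 0.5 * sqrt(100 / pi))
  expect_equal(smoothing_sigma(100, 0.5), 2.8209, tolerance = 1e-4)
  expect_error(smoothing_sigma(0), "positive")
})

test_that("Gaussian smoothing preserves constants and impulse peaks", {
  cst <- matrix(0.7, 32, 32)
  out <- smooth_distance(cst, avg_area = 100)
  expect_equal(out, cst, tolerance = 1e-12)
  imp <- matrix(0, 33, 33); imp[17, 17] <- 1
  sm <- smooth_distance(imp, avg_area = 100)
  expect_equal(which(sm == max(sm)), which(imp == 1))
  expect_true(all(sm >= 0))
  # negative predictions are clamped before smoothing
  neg <- matrix(-1, 8, 8)
  expect_equal(smooth_distance(neg, avg_area = 50), matrix(0, 8, 8))
})

test_that("find_seeds detects isolated bumps and respects separation", {
  h <- 64L
  expect_equal(max(find_seeds(matrix(0, h, h), matrix(1, h, h), 100)), 0L)
  grid <- expand.grid(r = 1:h, c = 1:h)
  bump <- function(cr, cc, s = 5)
    matrix(exp(-((grid$r - cr)^2 + (grid$c - cc)^2) / (2 * s^2)), h, h)
  fg <- matrix(1, h, h)
  one <- bump(30, 30)
  s1 <- find_seeds(one, fg, avg_area = 100)
  expect_equal(sum(s1 > 0), 1L)
  expect_equal(which(s1 == 1L), which(one == max(one)))
  # two bumps 3 equivalent radii apart -> 2 seeds at the two peaks;
  # oracle: exhaustive scan for local maxima over the full map
  r_eq <- sqrt(100 / pi)
  two <- bump(20, 20) + bump(20, 20 + round(3 * r_eq))
  s2 <- find_seeds(two, fg, avg_area = 100)
  expect_equal(sum(s2 > 0), 2L)
  peaks <- which(s2 > 0, arr.ind = TRUE)
  # exhaustive oracle: a seed must beat every pixel within the window
  win <- ceiling(r_eq)
  is_peak <- function(i, j) {
    nb <- two[max(1, i - win):min(h, i + win), max(1, j - win):min(h, j + win)]
    two[i, j] == max(nb)
  }
  expect_true(all(apply(peaks, 1, function(p) is_peak(p[1], p[2]))))
})

test_that("seeds stay inside the foreground and above the peak floor", {
  h <- 64L
  grid <- expand.grid(r = 1:h, c = 1:h)
  big <- matrix(exp(-((grid$r - 20)^2 + (grid$c - 20)^2) / 50), h, h)
  tiny <- 0.05 * matrix(exp(-((grid$r - 50)^2 + (grid$c - 50)^2) / 50), h, h)
  fg <- matrix(0, h, h); fg[1:40, 1:40] <- 1
  s <- find_seeds(big + tiny, fg, avg_area = 80)
  expect_true(all(fg[s > 0] == 1)) # restricted to foreground
  # the tiny bump is below 10% of the maximum -> no second seed
  expect_equal(sum(s > 0), 1L)
})

test_that("watershed floods blobs from seeds and honors the orphan rule", {
  h <- 40L
  blob <- disk_mask(h, h, 20, 20, 8)
  sm <- make_distance_map(blob)
  seeds <- matrix(0L, h, h); seeds[20, 20] <- 1L
  lab <- watershed_instances(sm, seeds, blob > 0)
  expect_equal(max(lab), 1L)
  expect_identical(lab > 0, blob > 0L)
  # dumbbell: two disks joined by a thin bridge, two seeds -> partition
  dumb <- matrix(0L, h, h)
  dumb[disk_mask(h, h, 20, 12, 7) > 0] <- 1L
  dumb[disk_mask(h, h, 20, 30, 7) > 0] <- 1L
  dumb[19:21, 12:30] <- 1L
  smd <- make_distance_map(dumb)
  seeds2 <- matrix(0L, h, h); seeds2[20, 12] <- 1L; seeds2[20, 30] <- 2L
  lab2 <- watershed_instances(smd, seeds2, dumb > 0)
  expect_equal(max(lab2), 2L)
  expect_identical(lab2 > 0, dumb > 0L)
  expect_equal(lab2[20, 12], 1L)
  expect_equal(lab2[20, 30], 2L)
  # zero seeds: the whole blob becomes one orphan instance
  lab3 <- watershed_instances(sm, matrix(0L, h, h), blob > 0)
  expect_equal(max(lab3), 1L)
  expect_identical(lab3 > 0, blob > 0L)
  expect_error(watershed_instances(sm, seeds * 0L + 1L, blob > 0),
               "foreground")
})

test_that("refine_instances enforces the 30-px rule and fills holes", {
  m <- matrix(0L, 60, 60)
  # area 29 (to remove) and area 30 (to keep)
  m[2:30, 2][1:29] <- 1L
  m[2:31, 5][1:30] <- 2L
  # 500-ish instance with an internal hole
  m[20:44, 20:39] <- 3L
  m[30, 30] <- 0L
  out <- refine_instances(m, merge_config())
  areas <- nucseg:::instance_areas(out)
  expect_equal(length(areas), 2L)
  expect_equal(sort(areas), c(30L, 25L * 20L))
  expect_true(all(out[20:44, 20:39] > 0L)) # hole filled
  # idempotence
  expect_identical(refine_instances(out, merge_config()), out)
})

test_that("hole filling only absorbs holes enclosed by a single instance", {
  m <- matrix(0L, 20, 40)
  m[4:16, 4:16] <- 1L; m[8:12, 8:12] <- 0L     # true hole in instance 1
  m[4:16, 24:36] <- 2L; m[8:12, 28:32] <- 0L   # hole in instance 2
  out <- refine_instances(m, merge_config(min_instance_area = 0L))
  expect_true(all(out[8:12, 8:12] == 1L))
  expect_true(all(out[8:12, 28:32] == 2L))
  # a bay open to the border is not a hole
  bay <- matrix(0L, 20, 20); bay[5:15, 5:15] <- 1L; bay[9:11, 1:10] <- 0L
  bay <- nucseg:::relabel_contiguous(bay)
  out2 <- refine_instances(bay, merge_config(min_instance_area = 0L))
  expect_true(all(out2[10, 1:9] == 0L))
})

test_that("class assignment is a per-instance majority vote with tie-break", {
  lab <- matrix(0L, 10, 10)
  lab[2:4, 2:6] <- 1L # 15 px
  lab[7:9, 2:6] <- 2L
  k1 <- 5L
  probs <- array(0, c(10, 10, k1))
  probs[, , 1] <- 1 # background by default
  # instance 1: 9 px class 2 (cols 4:6), 6 px class 1 (cols 2:3)
  set_pix <- function(arr, r, c, cls) {
    arr[r, c, ] <- 0; arr[r, c, cls + 1L] <- 1; arr
  }
  for (j in 2:6) for (i in 2:4)
    probs <- set_pix(probs, i, j, if (j <= 3) 1L else 2L)
  # instance 2: 8 px class 1, 6 px class 3, 1 px class 4
  for (j in 2:6) for (i in 7:9)
    probs <- set_pix(probs, i, j, if (j <= 3) 3L else 1L)
  probs <- set_pix(probs, 9, 6, 4L)
  res <- assign_classes(lab, probs)
  expect_equal(res$table$class[1L], 2L)
  expect_equal(res$table$class[2L], 1L)
  # exact 2-vs-2 tie between classes 1 and 3 breaks toward the lowest index
  labt <- matrix(0L, 6, 6); labt[2:3, 2:3] <- 1L
  pt <- array(0, c(6, 6, 5)); pt[, , 1] <- 1
  pt <- set_pix(pt, 2, 2, 3L); pt <- set_pix(pt, 2, 3, 1L)
  pt <- set_pix(pt, 3, 2, 1L); pt <- set_pix(pt, 3, 3, 3L)
  expect_equal(assign_classes(labt, pt)$table$class, 1L)
  expect_equal(res$table$vote_fraction[1L], 9 / 15)
  expect_true(all(res$class_mask[lab == 1L] == 2L))
  expect_true(all(res$class_mask[lab == 0L] == 0L))
  # uniform instance keeps its class
  lab3 <- matrix(0L, 6, 6); lab3[2:4, 2:4] <- 1L
  p3 <- array(0, c(6, 6, 5)); p3[, , 1] <- 1
  for (i in 2:4) for (j in 2:4) p3 <- set_pix(p3, i, j, 4L)
  expect_equal(assign_classes(lab3, p3)$table$class, 4L)
})

test_that("TTA equals plain forward for constant models and averages maps", {
  net <- constant_dual_net(distance = 0.3, fg_prob = 0.2)
  x <- array(stats::runif(64 * 64 * 3), c(64, 64, 3))
  plain <- predict_with_tta(net, x, tta = FALSE)
  avg <- predict_with_tta(net, x, tta = TRUE)
  expect_equal(avg$distance, plain$distance, tolerance = 1e-12)
  expect_equal(avg$foreground_prob, plain$foreground_prob, tolerance = 1e-12)
  expect_equal(unique(as.vector(plain$foreground_prob)), 0.2,
               tolerance = 1e-12)
  # tta = FALSE is bitwise the plain forward pass
  expect_identical(predict_with_tta(net, x, tta = FALSE),
                   nucseg:::net_forward(net, x))
})

test_that("TTA inverts its geometric transforms on a non-constant model", {
  net <- build_dual_decoder(tiny_net_config(), seed = 6L)
  x <- array(stats::runif(32 * 48 * 3), c(32, 48, 3)) # non-square
  out <- predict_with_tta(net, x, tta = TRUE)
  expect_equal(dim(out$distance), c(32L, 48L))
  # manual average of the three inverse-transformed passes
  f <- nucseg:::net_forward
  o1 <- f(net, x)
  o2 <- lapply(f(net, nucseg:::rot90_ccw(x)), nucseg:::rot90_cw)
  o3 <- lapply(f(net, nucseg:::flip_horizontal(x)), nucseg:::flip_horizontal)
  expect_equal(out$distance, (o1$distance + o2$distance + o3$distance) / 3,
               tolerance = 1e-12)
})

test_that("ensembles average member outputs and validate inputs", {
  m1 <- constant_dual_net(fg_prob = 0.2)
  m2 <- constant_dual_net(fg_prob = 0.4)
  x <- array(0.5, c(32, 32, 3))
  avg <- ensemble_predict(list(m1, m2), x)
  expect_equal(unique(as.vector(avg$foreground_prob)), 0.3, tolerance = 1e-9)
  # permutation invariance
  avg2 <- ensemble_predict(list(m2, m1), x)
  expect_equal(avg$foreground_prob, avg2$foreground_prob, tolerance = 1e-12)
  # singleton ensemble equals predict_with_tta
  expect_equal(ensemble_predict(list(m1), x)$foreground_prob,
               predict_with_tta(m1, x)$foreground_prob)
  expect_error(ensemble_predict(list(), x), "at least one")
  m3 <- build_dual_decoder(network_config(depth = 3, base_filters = 4), 1L)
  expect_error(ensemble_predict(list(m1, m3), x), "architecture")
})

test_that("pad_to_valid reaches the nearest multiple of 32 and round-trips", {
  img250 <- array(0.5, c(250, 250, 3))
  p <- pad_to_valid(img250)
  expect_equal(dim(p$image), c(256L, 256L, 3L))
  expect_equal(p$record$padded_side, 250L)
  img8235 <- array(0.5, c(82, 35, 3))
  p2 <- pad_to_valid(img8235)
  expect_equal(p2$record$padded_side, 82L)
  expect_equal(dim(p2$image), c(96L, 96L, 3L))
  # white padding (sampled away from the bilinear transition at ~col 41)
  expect_true(all(abs(p2$image[, 60:96, ] - 1) < 1e-9))
  # already-valid sizes round-trip label maps exactly
  lab <- random_rect_mask(256, 256, 8, 1)
  p3 <- pad_to_valid(array(0.5, c(256, 256, 3)))
  expect_identical(unpad_labels(lab, p3$record), lab)
  # general round trip restores the original shape
  lab2 <- matrix(1L, 96, 96)
  back <- unpad_labels(lab2, p2$record)
  expect_equal(dim(back), c(82L, 35L))
})

test_that("the merge stage is deterministic end to end", {
  s <- generate_nuclei_image(tiny_fixture(seed = 21))
  d <- make_distance_map(s$labels)
  b <- suppressWarnings(refine_binary_mask(s$labels))
  l1 <- merge_outputs(d, b)
  l2 <- merge_outputs(d, b)
  expect_identical(l1, l2)
  areas <- nucseg:::instance_areas(l1)
  expect_true(all(areas >= merge_config()$min_instance_area))
  for (k in seq_len(max(l1))) # 4-connected outputs
    expect_equal(max(nucseg:::.label_components(l1 == k, 4L)), 1L)
})
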