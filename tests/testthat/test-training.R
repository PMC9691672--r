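test_that("the step learning-rate schedule matches the published recipe", {
  cfg <- train_config()
  expect_equal(lr_schedule(0, cfg), 1e-3)
  expect_equal(lr_schedule(19, cfg), 1e-3)
  expect_equal(lr_schedule(20, cfg), 1e-4)
  expect_equal(lr_schedule(119, cfg), 1e-8)
  expect_error(lr_schedule(120, cfg), "epoch")
  expect_error(lr_schedule(-1, cfg), "epoch")
  # non-increasing over the full range
  lrs <- lr_schedule(0:119, cfg)
  expect_true(all(diff(lrs) <= 0))
})

test_that("grouped folds keep each organ's samples together", {
  ids <- sprintf("img%02d", 1:30)
  organs <- rep(sprintf("organ%02d", 1:10), each = 3L)
  folds <- make_cv_folds(ids, k = 10L, seed = 4L, group_by = organs)
  expect_length(folds, 10L)
  for (f in folds) {
    expect_length(f$test_ids, 3L)
    expect_length(unique(organs[match(f$test_ids, ids)]), 1L)
    expect_length(intersect(f$train_ids, f$test_ids), 0L)
  }
  # test sets tile the dataset exactly once
  all_test <- unlist(lapply(folds, `[[`, "test_ids"))
  expect_setequal(all_test, ids)
  expect_equal(length(all_test), 30L)
  # a group never straddles a fold boundary
  for (f in folds)
    expect_length(intersect(unique(organs[match(f$train_ids, ids)]),
                            f$group_key), 0L)
})

test_that("random k-fold partition balances test sizes deterministically", {
  ids <- seq_len(665)
  folds <- make_cv_folds(ids, k = 5L, seed = 1L)
  expect_equal(vapply(folds, function(f) length(f$test_ids), 0L),
               rep(133L, 5L))
  folds2 <- make_cv_folds(ids, k = 5L, seed = 1L)
  expect_identical(folds, folds2)
  folds3 <- make_cv_folds(ids, k = 5L, seed = 2L)
  expect_false(identical(folds, folds3))
  expect_error(make_cv_folds(1:3, k = 5L), "exceeds")
  expect_error(make_cv_folds(c(1, 1, 2), k = 2L), "unique")
})

test_that("class-balanced sampling upweights rare classes", {
  # counts mirroring a strongly imbalanced 4-class dataset
  set.seed(2)
  samples <- lapply(1:4, function(i) {
    s <- generate_nuclei_image(fixture_config(
      height = 160L, width = 160L, n_nuclei = 20L, radius_range = c(5, 8),
      n_classes = 4L, class_proportions = c(0.45, 0.45, 0.05, 0.05),
      seed = 600L + i))
    list(image = s$image, labels = s$labels, classes = s$classes)
  })
  res <- sample_class_balanced_patches(samples, patch_size = 48L,
                                       n_patches = 100L, seed = 3L)
  expect_length(res$patches, 100L)
  # per-nucleus weights rank rare classes above common ones
  wts <- tapply(res$table$weight, res$table$class, mean)
  counts <- table(factor(res$table$class, levels = 1:4))
  present <- counts > 0
  expect_true(all(diff(rank(wts[present])) *
                  diff(rank(-as.numeric(counts[present]))) >= 0))
  # patches fit and contain their center nucleus
  for (p in res$patches[1:10]) {
    expect_equal(dim(p$labels), c(48L, 48L))
    expect_true(p$instance %in% p$labels)
  }
  # determinism
  res2 <- sample_class_balanced_patches(samples, patch_size = 48L,
                                        n_patches = 100L, seed = 3L)
  expect_identical(res$table, res2$table)
})

test_that("equal class counts give equal expected patch frequencies", {
  # balanced fixture; compare empirical draws against a multinomial oracle
  samples <- lapply(1:3, function(i) {
    s <- generate_nuclei_image(fixture_config(
      height = 160L, width = 160L, n_nuclei = 24L, radius_range = c(5, 7),
      n_classes = 4L, class_proportions = rep(0.25, 4), seed = 700L + i))
    list(image = s$image, labels = s$labels, classes = s$classes)
  })
  res <- sample_class_balanced_patches(samples, patch_size = 48L,
                                       n_patches = 400L, seed = 5L)
  drawn <- table(factor(vapply(res$patches, `[[`, 0L, "class"), levels = 1:4))
  # oracle: expected frequency per class = sum of its normalized weights
  expected <- tapply(res$table$weight, factor(res$table$class, levels = 1:4),
                     sum)
  expected[is.na(expected)] <- 0
  # binomial 4-sigma envelope around each expectation
  for (c in 1:4) {
    p <- expected[c]
    expect_lt(abs(drawn[c] / 400 - p), 4 * sqrt(p * (1 - p) / 400) + 1e-9)
  }
})

test_that("a class with zero instances is excluded with a warning", {
  s <- generate_nuclei_image(fixture_config(
    height = 96L, width = 96L, n_nuclei = 6L, radius_range = c(5, 7),
    n_classes = 4L, class_proportions = c(0.5, 0.5, 0, 0), seed = 8L))
  samples <- list(list(image = s$image, labels = s$labels,
                       classes = s$classes))
  expect_warning(
    res <- sample_class_balanced_patches(samples, patch_size = 48L,
                                         n_patches = 20L, seed = 1L),
    "excluded")
  expect_length(res$patches, 20L)
  expect_true(all(vapply(res$patches, `[[`, 0L, "class") %in% 1:2))
})

test_that("short training runs record history and are reproducible", {
  ds <- generate_dataset(4L, tiny_fixture(), seed = 50L)
  data <- lapply(ds$samples, function(s) prepare_sample(s$image, s$labels))
  net <- build_dual_decoder(network_config(depth = 2L, base_filters = 4L,
                                           dropout_rate = 0.1))
  cfg <- train_config(epochs = 2L, batch_size = 2L, seed = 9L)
  m1 <- train_network(net, data, cfg)
  expect_s3_class(m1, "nucseg_model")
  expect_equal(nrow(m1$history), 2L)
  expect_true(all(c("epoch", "lr", "loss", "mse", "dice", "bce") %in%
                  names(m1$history)))
  m2 <- train_network(net, data, cfg)
  expect_equal(m1$history$loss, m2$history$loss, tolerance = 1e-12)
  expect_equal(m1$net$params$dist_head_w, m2$net$params$dist_head_w,
               tolerance = 1e-12)
  expect_error(train_network(net, list(), cfg), "empty")
})

test_that("fine-tuning resumes from checkpoint weights", {
  ds <- generate_dataset(2L, tiny_fixture(), seed = 60L)
  data <- lapply(ds$samples, function(s) prepare_sample(s$image, s$labels))
  cfg0 <- network_config(depth = 2L, base_filters = 4L, dropout_rate = 0)
  net <- build_dual_decoder(cfg0)
  m <- train_network(net, data, train_config(epochs = 1L, batch_size = 2L,
                                             seed = 3L))
  ck <- withr::local_tempfile(fileext = ".rds")
  nucseg:::save_checkpoint(m$net, ck)
  # checkpoint weights are used verbatim before the first step
  loaded <- nucseg:::load_checkpoint(ck)
  x <- ds$samples[[1L]]$image
  expect_identical(predict(loaded, x), predict(m$net, x))
  # architecture mismatch is rejected
  other <- build_dual_decoder(network_config(depth = 3L, base_filters = 4L))
  expect_error(
    train_network(other, data,
                  train_config(epochs = 1L, pretrain_checkpoint = ck)),
    "architecture")
  # fine-tuning starts from the checkpoint, not from re-initialization
  m2 <- train_network(net, data,
                      train_config(epochs = 1L, batch_size = 2L, seed = 99L,
                                   pretrain_checkpoint = ck))
  expect_lt(m2$history$loss[1L], m$history$loss[1L] + 0.5)
})

test_that("classifier training consumes one-hot targets", {
  cfgf <- tiny_fixture(n_classes = 2L, class_proportions = c(0.5, 0.5),
                       seed = 70L)
  ds <- generate_dataset(2L, cfgf, seed = 70L)
  data <- lapply(ds$samples, function(s)
    prepare_sample(s$image, s$labels, classes = s$classes, n_classes = 2L))
  net <- build_classifier(network_config(depth = 2L, base_filters = 4L,
                                         dropout_rate = 0, n_classes = 2L))
  m <- train_network(net, data, train_config(epochs = 2L, batch_size = 2L,
                                             seed = 4L))
  expect_equal(nrow(m$history), 2L)
  expect_true(all(is.finite(m$history$loss)))
  # targets missing the one-hot channel error out
  bad <- lapply(ds$samples, function(s) prepare_sample(s$image, s$labels))
  expect_error(train_network(net, bad, train_config(epochs = 1L)),
               "class_onehot")
})
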