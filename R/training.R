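# Optimization recipe: Adam with a step learning-rate schedule, Xavier
# initialization, grouped or random cross-validation folds, class-balanced
# patch extraction and the pre-train/fine-tune flow.

#' Training configuration
#'
#' Defaults follow the published recipe: 120 epochs of Adam at an initial
#' learning rate of 0.001, dropped by a factor of 0.1 after every 20 epochs,
#' Xavier initialization, no early stopping (the last epoch's weights are
#' the model).
#'
#' @param epochs Number of epochs (>= 1).
#' @param initial_lr Initial learning rate (> 0).
#' @param lr_drop_factor Multiplicative drop, in `(0, 1]`.
#' @param lr_drop_every Epochs between drops.
#' @param batch_size Mini-batch size (gradients are averaged over the
#'   batch). The value is a free parameter of this implementation; 4 fits
#'   full 512 x 512 images in memory on modest hardware.
#' @param seed Seed controlling initialization, shuffling, augmentation and
#'   dropout.
#' @param augment Optional [augment_config()] applied to each sample per
#'   epoch (NULL disables augmentation).
#' @param pretrain_checkpoint Optional path to a checkpoint to fine-tune
#'   from; its architecture config must match.
#' @export
train_config <- function(epochs = 120L, initial_lr = 0.001,
                         lr_drop_factor = 0.1, lr_drop_every = 20L,
                         batch_size = 4L, seed = 1L, augment = NULL,
                         pretrain_checkpoint = NULL) {
  epochs <- as.integer(epochs)
  if (epochs < 1L) stop("epochs must be >= 1")
  if (initial_lr <= 0) stop("initial_lr must be positive")
  if (lr_drop_factor <= 0 || lr_drop_factor > 1)
    stop("lr_drop_factor must be in (0, 1]")
  if (lr_drop_every < 1L) stop("lr_drop_every must be >= 1")
  if (batch_size < 1L) stop("batch_size must be >= 1")
  structure(list(epochs = epochs, initial_lr = initial_lr,
                 lr_drop_factor = lr_drop_factor,
                 lr_drop_every = as.integer(lr_drop_every),
                 batch_size = as.integer(batch_size), seed = as.integer(seed),
                 init = "xavier", augment = augment,
                 pretrain_checkpoint = pretrain_checkpoint),
            class = "nucseg_train_config")
}

#' Step learning-rate schedule
#'
#' `initial_lr * lr_drop_factor ^ floor(epoch / lr_drop_every)` for 0-based
#' `epoch`; with the defaults, 1e-3 for epochs 0-19, 1e-4 for 20-39, and so
#' on down to 1e-8 at epoch 119.
#'
#' @param epoch 0-based epoch index in `[0, epochs)`.
#' @param config A [train_config()].
#' @export
lr_schedule <- function(epoch, config = train_config()) {
  if (any(epoch < 0) || any(epoch >= config$epochs))
    stop(sprintf("epoch must lie in [0, %d)", config$epochs))
  config$initial_lr * config$lr_drop_factor^(epoch %/% config$lr_drop_every)
}

#' Cross-validation folds, optionally grouped
#'
#' With `group_by`, a leave-groups-out partition: groups (e.g. organs) are
#' shuffled under the seed and distributed round-robin over `k` folds, so
#' each fold's test set is the union of its groups' samples and no group is
#' ever split across a fold boundary. Without `group_by`, a seeded random
#' k-fold partition of samples.
#'
#' @param sample_ids Vector of sample identifiers.
#' @param k Number of folds.
#' @param seed Integer seed.
#' @param group_by Optional vector of group labels aligned with
#'   `sample_ids` (NULL for ungrouped folds).
#' @return List of `k` folds, each a list with `fold_id`, `train_ids`,
#'   `test_ids`, `group_key`.
#' @export
make_cv_folds <- function(sample_ids, k, seed = 1L, group_by = NULL) {
  k <- as.integer(k)
  if (anyDuplicated(sample_ids)) stop("sample_ids must be unique")
  if (!is.null(group_by)) {
    if (length(group_by) != length(sample_ids))
      stop("group_by must align with sample_ids")
    groups <- unique(group_by)
    if (k > length(groups))
      stop(sprintf("k = %d exceeds the %d distinct groups", k, length(groups)))
    perm <- with_seed(seed, sample(length(groups)))
    assignment <- rep_len(seq_len(k), length(groups))[order(perm)]
    lapply(seq_len(k), function(f) {
      gs <- groups[assignment == f]
      test <- sample_ids[group_by %in% gs]
      list(fold_id = f, train_ids = setdiff(sample_ids, test),
           test_ids = test, group_key = gs)
    })
  } else {
    if (k > length(sample_ids))
      stop(sprintf("k = %d exceeds the %d samples", k, length(sample_ids)))
    perm <- with_seed(seed, sample(length(sample_ids)))
    assignment <- rep_len(seq_len(k), length(sample_ids))[order(perm)]
    lapply(seq_len(k), function(f) {
      test <- sample_ids[assignment == f]
      list(fold_id = f, train_ids = setdiff(sample_ids, test),
           test_ids = test, group_key = NA)
    })
  }
}

#' Class-balanced nucleus-centered patch extraction
#'
#' Builds the table of all nuclei across the class-annotated samples, weights
#' each nucleus inversely to its class's global instance count (so
#' underrepresented classes are sampled more often), and draws `n_patches`
#' nuclei with replacement. Each patch is centered on its nucleus centroid
#' and shifted inside the image near borders. Classes without instances are
#' excluded with a warning. Deterministic under `seed`.
#'
#' @param samples List of samples, each with `image`, `labels`, `classes`.
#' @param patch_size Patch side in pixels (must fit in every image).
#' @param n_patches Number of patches to draw.
#' @param seed Integer seed.
#' @param n_classes Number of classes.
#' @return List with `patches` (each: image/labels/classes subarrays plus
#'   sample index, instance id, class) and `table` (the weighted nucleus
#'   table).
#' @export
sample_class_balanced_patches <- function(samples, patch_size, n_patches,
                                          seed = 1L, n_classes = 4L) {
  patch_size <- as.integer(patch_size)
  rows <- list()
  for (si in seq_along(samples)) {
    s <- samples[[si]]
    if (min(dim(s$labels)) < patch_size)
      stop("patch_size exceeds an image side")
    for (k in label_ids(s$labels)) {
      sel <- which(s$labels == k, arr.ind = TRUE)
      rows[[length(rows) + 1L]] <- data.frame(
        sample = si, instance = k,
        class = as.integer(s$classes[sel[1L, 1L], sel[1L, 2L]]),
        center_row = mean(sel[, 1L]), center_col = mean(sel[, 2L]))
    }
  }
  tab <- do.call(rbind, rows)
  counts <- tabulate(tab$class, nbins = n_classes)
  empty <- which(counts == 0L)
  if (length(empty))
    warning(sprintf("class(es) %s have no instances and are excluded",
                    paste(empty, collapse = ", ")))
  w <- ifelse(counts[tab$class] > 0, 1 / counts[tab$class], 0)
  tab$weight <- w / sum(w)
  draw <- with_seed(seed, sample(nrow(tab), n_patches, replace = TRUE,
                                 prob = tab$weight))
  patches <- lapply(draw, function(i) {
    s <- samples[[tab$sample[i]]]
    h <- nrow(s$labels); wd <- ncol(s$labels)
    half <- patch_size %/% 2L
    r0 <- min(max(round(tab$center_row[i]) - half, 1L), h - patch_size + 1L)
    c0 <- min(max(round(tab$center_col[i]) - half, 1L), wd - patch_size + 1L)
    rr <- r0:(r0 + patch_size - 1L); cc <- c0:(c0 + patch_size - 1L)
    list(image = s$image[rr, cc, , drop = FALSE],
         labels = s$labels[rr, cc, drop = FALSE],
         classes = s$classes[rr, cc, drop = FALSE],
         sample = tab$sample[i], instance = tab$instance[i],
         class = tab$class[i])
  })
  list(patches = patches, table = tab)
}

adam_init <- function(params)
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L,
       beta1 = 0.9, beta2 = 0.999, eps = 1e-8)

adam_step <- function(params, grads, state, lr) {
  state$t <- state$t + 1L
  bc1 <- 1 - state$beta1^state$t
  bc2 <- 1 - state$beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- state$beta1 * state$m[[nm]] + (1 - state$beta1) * g
    state$v[[nm]] <- state$beta2 * state$v[[nm]] + (1 - state$beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + state$eps)
  }
  list(params = params, state = state)
}

sample_targets <- function(s, type) {
  if (type == "dual")
    list(distance = s$distance, binary = s$refined_binary)
  else {
    if (is.null(s$class_onehot)) stop("classifier training needs class_onehot")
    list(onehot = s$class_onehot)
  }
}

#' Train a network
#'
#' Mini-batch Adam over prepared training samples, with the step learning
#' rate schedule of [lr_schedule()], per-epoch reshuffling, optional
#' augmentation, and all randomness (initialization, shuffling,
#' augmentation, dropout) derived from the config seed. Without a
#' pre-training checkpoint the weights are re-initialized (Xavier) under
#' that seed; with one, training fine-tunes the checkpoint weights.
#' Non-finite losses abort with a diagnostic naming the epoch and batch.
#'
#' @param model A `nucseg_net` from [build_dual_decoder()] or
#'   [build_classifier()] (defines the architecture and model type).
#' @param data List of `nucseg_sample` objects (see [prepare_sample()]).
#' @param config A [train_config()].
#' @return An object of class `nucseg_model`: the trained network plus a
#'   per-epoch `history` data frame (loss components, learning rate) and the
#'   configs used.
#' @export
train_network <- function(model, data, config = train_config()) {
  stopifnot(inherits(model, "nucseg_net"))
  if (!length(data)) stop("training data is empty")
  net <- model
  if (!is.null(config$pretrain_checkpoint)) {
    ck <- load_checkpoint(config$pretrain_checkpoint)
    if (!identical(unclass(ck$config), unclass(net$config)) ||
        !identical(ck$type, net$type))
      stop("checkpoint architecture does not match the model configuration")
    net$params <- ck$params
  } else {
    net <- new_nucseg_net(net$config, net$type, config$seed)
  }
  state <- adam_init(net$params)
  n <- length(data)
  hist <- vector("list", config$epochs)
  with_seed(config$seed + 1L, {
    for (epoch in seq_len(config$epochs) - 1L) {
      lr <- lr_schedule(epoch, config)
      ord <- sample(n)
      comp_sum <- NULL; loss_sum <- 0; n_seen <- 0L
      b0 <- 1L
      batch_idx <- 0L
      while (b0 <= n) {
        batch <- ord[b0:min(n, b0 + config$batch_size - 1L)]
        batch_idx <- batch_idx + 1L
        gacc <- NULL
        for (si in batch) {
          s <- data[[si]]
          if (!is.null(config$augment))
            s <- augment_sample(s, config$augment,
                                seed = sample.int(.Machine$integer.max, 1L))
          fw <- net_forward(net, s$image, training = TRUE)
          tg <- sample_targets(s, net$type)
          lg <- if (net$type == "dual")
            dual_loss_grad(fw[c("distance", "foreground_prob")],
                           tg$distance, tg$binary)
          else class_loss_grad(fw["class_probs"], tg$onehot)
          if (!is.finite(lg$loss))
            stop(sprintf("non-finite loss at epoch %d, batch %d",
                         epoch + 1L, batch_idx))
          g <- net_backward(net, fw$cache, lg$head_grads)
          gacc <- if (is.null(gacc)) g else
            Map(`+`, gacc, g)
          loss_sum <- loss_sum + lg$loss
          comp_sum <- if (is.null(comp_sum)) lg$components else
            comp_sum + lg$components
          n_seen <- n_seen + 1L
        }
        gacc <- lapply(gacc, `/`, length(batch))
        upd <- adam_step(net$params, gacc, state, lr)
        net$params <- upd$params
        state <- upd$state
        b0 <- b0 + config$batch_size
      }
      hist[[epoch + 1L]] <- data.frame(
        epoch = epoch + 1L, lr = lr, loss = loss_sum / n_seen,
        t(comp_sum / n_seen))
    }
  })
  history <- do.call(rbind, hist)
  structure(list(net = net, type = net$type, history = history,
                 train_config = config,
                 adam = c(beta1 = state$beta1, beta2 = state$beta2,
                          eps = state$eps),
                 n_samples = n),
            class = "nucseg_model")
}

#' @export
print.nucseg_model <- function(x, ...) {
  cat(sprintf(
    "<nucseg_model> trained %s network (%d epochs on %d samples)\n",
    x$type, nrow(x$history), x$n_samples))
  cat(sprintf("  final loss %.4f (lr %.2g)\n",
              x$history$loss[nrow(x$history)],
              x$history$lr[nrow(x$history)]))
  invisible(x)
}

#' @export
summary.nucseg_model <- function(object, ...) {
  h <- object$history
  cat(sprintf("Trained %s network: depth %d, %d base filters, %s parameters\n",
              object$type, object$net$config$depth,
              object$net$config$base_filters,
              format(n_parameters(object$net), big.mark = ",")))
  cat(sprintf("Adam (beta1 %.3g, beta2 %.3g, eps %.1g), %d epochs, batch %d\n",
              object$adam["beta1"], object$adam["beta2"], object$adam["eps"],
              nrow(h), object$train_config$batch_size))
  cat(sprintf("Loss: %.4f (epoch 1) -> %.4f (epoch %d)\n",
              h$loss[1L], h$loss[nrow(h)], nrow(h)))
  invisible(object)
}

#' Predict from a trained model
#'
#' `type = "maps"` returns the raw output maps; `type = "instances"` runs
#' the full merge ([merge_outputs()]) and returns the instance label mask.
#'
#' @param object A `nucseg_model`.
#' @param image H x W x 3 input image.
#' @param type Output kind.
#' @param tta Test-time augmentation.
#' @param merge A [merge_config()] for `type = "instances"`.
#' @param ... Unused.
#' @export
predict.nucseg_model <- function(object, image, type = c("maps", "instances"),
                                 tta = FALSE, merge = merge_config(), ...) {
  type <- match.arg(type)
  maps <- predict_with_tta(object$net, image, tta = tta)
  if (type == "maps" || object$type != "dual") return(maps)
  merge_outputs(maps$distance, maps$foreground_prob, merge)
}

#' Plot the training history
#'
#' Loss (and its components) against epoch on a log-scaled y axis.
#' @param x A `nucseg_model`.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.nucseg_model <- function(x, ...) {
  h <- x$history
  comp <- setdiff(names(h), c("epoch", "lr"))
  graphics::matplot(h$epoch, h[, comp, drop = FALSE], type = "l", lty = 1,
                    xlab = "epoch", ylab = "loss", log = "y", ...)
  graphics::legend("topright", legend = comp, col = seq_along(comp), lty = 1,
                   bty = "n")
  invisible(x)
}

#' Segment an image of arbitrary size end to end
#'
#' Pads the image to a network-valid square ([pad_to_valid()]), predicts
#' with the model or ensemble (optionally with TTA), merges the output maps
#' into instances, and maps the labels back to the original geometry
#' ([unpad_labels()]). When a classifier is supplied, instance classes are
#' assigned by majority vote at the prediction scale.
#'
#' @param models A `nucseg_model`/`nucseg_net` or list of them (ensemble).
#' @param image H x W x 3 image in `[0, 1]` (any size).
#' @param classifier Optional classifier model for class assignment.
#' @param tta Test-time augmentation.
#' @param merge A [merge_config()].
#' @return List with `labels` (instance mask at original size), and when a
#'   classifier is given, `classes` (per-instance table) and `class_mask`.
#' @export
segment_image <- function(models, image, classifier = NULL, tta = FALSE,
                          merge = merge_config()) {
  as_net <- function(m) if (inherits(m, "nucseg_model")) m$net else m
  nets <- if (inherits(models, c("nucseg_model", "nucseg_net")))
    list(as_net(models)) else lapply(models, as_net)
  padded <- pad_to_valid(image)
  maps <- ensemble_predict(nets, padded$image, tta = tta)
  lab <- merge_outputs(maps$distance, maps$foreground_prob, merge)
  out <- list(labels = unpad_labels(lab, padded$record))
  if (!is.null(classifier)) {
    cmaps <- predict_with_tta(as_net(classifier), padded$image, tta = tta)
    cls <- assign_classes(lab, cmaps$class_probs)
    out$classes <- cls$table
    out$class_mask <- unpad_labels(cls$class_mask, padded$record,
                                   relabel = FALSE)
  }
  out
}
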