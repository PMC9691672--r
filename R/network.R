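#' Network architecture configuration
#'
#' Describes the shared encoder/decoder layout used by both the dual-decoder
#' segmentation network and the single-decoder classification network. The
#' encoder has `depth` convolution blocks (two 3x3 convolutions with ReLU and
#' dropout between them, then 2x2 max pooling), a bottleneck block, and each
#' decoder mirrors it with transposed-convolution upsampling and skip
#' concatenations. Valid input sides are multiples of `2^depth` (32 at the
#' default depth of 5).
#'
#' @param depth Number of encoder blocks (and pooling stages). Default 5, so
#'   the overall stride is 32.
#' @param base_filters Filters in the first block, doubling per block.
#'   Default 64 mirrors the original U-Net; the `"small"` preset (8 filters,
#'   depth 3) is intended for CPU-scale experiments and tests.
#' @param dropout_rate Dropout rate between the two convolutions of every
#'   block, in `[0, 1)`.
#' @param n_classes Number of nucleus classes for the classifier head (the
#'   output adds one background channel).
#' @param input_channels Image channels (3 for RGB).
#' @param preset Either `"full"` (depth 5, 64 base filters) or `"small"`
#'   (depth 3, 8 base filters); explicit `depth`/`base_filters` override it.
#' @return An object of class `nucseg_config`.
#' @export
network_config <- function(depth = NULL, base_filters = NULL,
                           dropout_rate = 0.1, n_classes = 4L,
                           input_channels = 3L,
                           preset = c("full", "small")) {
  preset <- match.arg(preset)
  if (is.null(depth)) depth <- if (preset == "small") 3L else 5L
  if (is.null(base_filters)) base_filters <- if (preset == "small") 8L else 64L
  depth <- as.integer(depth); base_filters <- as.integer(base_filters)
  if (depth < 2L) stop("depth must be >= 2")
  if (base_filters < 4L) stop("base_filters must be >= 4")
  if (dropout_rate < 0 || dropout_rate >= 1) stop("dropout_rate must be in [0, 1)")
  if (n_classes < 0L) stop("n_classes must be non-negative")
  structure(list(depth = depth, base_filters = base_filters,
                 dropout_rate = dropout_rate, kernel_size = 3L,
                 n_classes = as.integer(n_classes),
                 input_channels = as.integer(input_channels),
                 stride = 2L^depth),
            class = "nucseg_config")
}

#' @export
print.nucseg_config <- function(x, ...) {
  cat(sprintf(
    "U-Net configuration: depth %d (stride %d), %d base filters, dropout %.2f\n",
    x$depth, x$stride, x$base_filters, x$dropout_rate))
  invisible(x)
}

xavier_limit <- function(fan_in, fan_out) sqrt(6 / (fan_in + fan_out))

xavier_conv3 <- function(cin, cout) {
  l <- xavier_limit(9 * cin, 9 * cout)
  matrix(stats::runif(9 * cin * cout, -l, l), 9L * cin, cout)
}

xavier_convt2 <- function(cin, cout) {
  l <- xavier_limit(4 * cin, 4 * cout)
  array(stats::runif(4 * cin * cout, -l, l), c(2L, 2L, cin, cout))
}

xavier_conv1 <- function(cin, cout) {
  l <- xavier_limit(cin, cout)
  matrix(stats::runif(cin * cout, -l, l), cin, cout)
}

decoder_names <- function(type) {
  if (type == "dual") c("dist", "bin") else "cls"
}

head_channels <- function(type, config) {
  if (type == "dual") c(dist = 1L, bin = 1L) else
    c(cls = config$n_classes + 1L)
}

init_params <- function(config, type) {
  depth <- config$depth
  fs <- config$base_filters * 2L^(0:(depth - 1L))
  fb <- config$base_filters * 2L^depth
  p <- list()
  cin <- config$input_channels
  for (i in seq_len(depth)) {
    p[[sprintf("enc%d_conv1_w", i)]] <- xavier_conv3(cin, fs[i])
    p[[sprintf("enc%d_conv1_b", i)]] <- numeric(fs[i])
    p[[sprintf("enc%d_conv2_w", i)]] <- xavier_conv3(fs[i], fs[i])
    p[[sprintf("enc%d_conv2_b", i)]] <- numeric(fs[i])
    cin <- fs[i]
  }
  p[["bott_conv1_w"]] <- xavier_conv3(fs[depth], fb)
  p[["bott_conv1_b"]] <- numeric(fb)
  p[["bott_conv2_w"]] <- xavier_conv3(fb, fb)
  p[["bott_conv2_b"]] <- numeric(fb)
  heads <- head_channels(type, config)
  for (dname in decoder_names(type)) {
    for (i in rev(seq_len(depth))) {
      up_in <- if (i == depth) fb else fs[i + 1L]
      p[[sprintf("%s_up%d_w", dname, i)]] <- xavier_convt2(up_in, fs[i])
      p[[sprintf("%s_up%d_b", dname, i)]] <- numeric(fs[i])
      p[[sprintf("%s_dec%d_conv1_w", dname, i)]] <- xavier_conv3(2L * fs[i], fs[i])
      p[[sprintf("%s_dec%d_conv1_b", dname, i)]] <- numeric(fs[i])
      p[[sprintf("%s_dec%d_conv2_w", dname, i)]] <- xavier_conv3(fs[i], fs[i])
      p[[sprintf("%s_dec%d_conv2_b", dname, i)]] <- numeric(fs[i])
    }
    p[[sprintf("%s_head_w", dname)]] <- xavier_conv1(fs[1L], heads[[dname]])
    p[[sprintf("%s_head_b", dname)]] <- numeric(heads[[dname]])
  }
  p
}

new_nucseg_net <- function(config, type, seed) {
  with_seed(seed, {
    params <- init_params(config, type)
  })
  structure(list(config = config, type = type, params = params,
                 init_seed = as.integer(seed)),
            class = "nucseg_net")
}

#' Build the dual-decoder segmentation network
#'
#' One U-Net encoder feeds two identical decoders: the distance decoder ends
#' in a 1-channel linear head regressing per-nucleus normalized distance
#' maps, the foreground decoder in a 1-channel sigmoid head. Skip
#' connections run from each encoder block to both decoders at matching
#' resolution. Weights are Xavier (Glorot uniform) initialized.
#'
#' @param config A [network_config()].
#' @param seed Integer seed for the weight initialization.
#' @return An object of class `nucseg_net` with `type = "dual"`.
#' @seealso [build_classifier()], [train_network()], [dual_loss()]
#' @export
build_dual_decoder <- function(config = network_config(), seed = 1L) {
  stopifnot(inherits(config, "nucseg_config"))
  new_nucseg_net(config, "dual", seed)
}

#' Build the nuclei classification network
#'
#' Same encoder as the dual-decoder model but with a single decoder ending in
#' a `(n_classes + 1)`-channel softmax head (background plus one channel per
#' nucleus class).
#'
#' @inheritParams build_dual_decoder
#' @return An object of class `nucseg_net` with `type = "classifier"`.
#' @export
build_classifier <- function(config = network_config(), seed = 1L) {
  stopifnot(inherits(config, "nucseg_config"))
  if (config$n_classes < 2L) stop("classifier requires n_classes >= 2")
  new_nucseg_net(config, "classifier", seed)
}

#' @export
print.nucseg_net <- function(x, ...) {
  np <- sum(vapply(x$params, length, 0L))
  cat(sprintf("<nucseg_net> %s model, depth %d, base filters %d, %s parameters\n",
              x$type, x$config$depth, x$config$base_filters,
              format(np, big.mark = ",")))
  invisible(x)
}

n_parameters <- function(net) sum(vapply(net$params, length, 0L))

check_input_shape <- function(net, x) {
  d <- dim(x)
  if (length(d) != 3L || d[3L] != net$config$input_channels)
    stop(sprintf("input must be H x W x %d", net$config$input_channels))
  s <- net$config$stride
  if (d[1L] %% s != 0L || d[2L] %% s != 0L)
    stop(sprintf("input sides must be multiples of %d (got %d x %d)",
                 s, d[1L], d[2L]))
  invisible(d)
}

# Full forward pass. When training = TRUE every intermediate needed by
# net_backward() is cached; dropout is active and consumes the R RNG stream.
net_forward <- function(net, x, training = FALSE) {
  check_input_shape(net, x)
  p <- net$params
  depth <- net$config$depth
  rate <- net$config$dropout_rate
  cache <- list()
  skips <- vector("list", depth)
  cur <- x
  for (i in seq_len(depth)) {
    c1 <- conv3_forward(cur, p[[sprintf("enc%d_conv1_w", i)]],
                        p[[sprintf("enc%d_conv1_b", i)]])
    r1 <- relu_forward(c1$out)
    dr <- dropout_forward(r1$out, rate, training)
    c2 <- conv3_forward(dr$out, p[[sprintf("enc%d_conv2_w", i)]],
                        p[[sprintf("enc%d_conv2_b", i)]])
    r2 <- relu_forward(c2$out)
    skips[[i]] <- r2$out
    pl <- maxpool2_forward(r2$out)
    cur <- pl$out
    if (training)
      cache[[sprintf("enc%d", i)]] <- list(c1 = c1, r1 = r1, dr = dr,
                                           c2 = c2, r2 = r2, pl = pl)
  }
  b1 <- conv3_forward(cur, p$bott_conv1_w, p$bott_conv1_b)
  br1 <- relu_forward(b1$out)
  bdr <- dropout_forward(br1$out, rate, training)
  b2 <- conv3_forward(bdr$out, p$bott_conv2_w, p$bott_conv2_b)
  br2 <- relu_forward(b2$out)
  if (training) cache$bott <- list(c1 = b1, r1 = br1, dr = bdr, c2 = b2, r2 = br2)
  bott_out <- br2$out

  out <- list()
  for (dname in decoder_names(net$type)) {
    cur <- bott_out
    for (i in rev(seq_len(depth))) {
      up <- convt2_forward(cur, p[[sprintf("%s_up%d_w", dname, i)]],
                           p[[sprintf("%s_up%d_b", dname, i)]])
      cat3 <- concat_channels(up$out, skips[[i]])
      c1 <- conv3_forward(cat3, p[[sprintf("%s_dec%d_conv1_w", dname, i)]],
                          p[[sprintf("%s_dec%d_conv1_b", dname, i)]])
      r1 <- relu_forward(c1$out)
      dr <- dropout_forward(r1$out, rate, training)
      c2 <- conv3_forward(dr$out, p[[sprintf("%s_dec%d_conv2_w", dname, i)]],
                          p[[sprintf("%s_dec%d_conv2_b", dname, i)]])
      r2 <- relu_forward(c2$out)
      if (training)
        cache[[sprintf("%s_dec%d", dname, i)]] <-
          list(up = up, c1 = c1, r1 = r1, dr = dr, c2 = c2, r2 = r2,
               n_up = dim(up$out)[3L])
      cur <- r2$out
    }
    hd <- conv1_forward(cur, p[[sprintf("%s_head_w", dname)]],
                        p[[sprintf("%s_head_b", dname)]])
    if (training) cache[[sprintf("%s_head", dname)]] <- hd
    out[[dname]] <- hd$out
  }

  res <- if (net$type == "dual") {
    list(distance = out$dist[, , 1L],
         foreground_prob = sigmoid(out$bin[, , 1L]))
  } else {
    list(class_probs = softmax_channels(out$cls))
  }
  if (training) res$cache <- cache
  res
}

# Backward pass. head_grads holds gradients with respect to the head
# PRE-ACTIVATIONS (z), i.e. sigmoid/softmax already folded into the loss
# gradient by the caller. Returns a named list of parameter gradients.
net_backward <- function(net, cache, head_grads) {
  p <- net$params
  depth <- net$config$depth
  g <- list()
  dskips <- vector("list", depth)
  dbott <- NULL
  for (dname in decoder_names(net$type)) {
    hd <- cache[[sprintf("%s_head", dname)]]
    dz <- head_grads[[dname]]
    if (length(dim(dz)) == 2L) dz <- array(dz, c(dim(dz), 1L))
    hb <- conv1_backward(dz, hd, p[[sprintf("%s_head_w", dname)]])
    g[[sprintf("%s_head_w", dname)]] <- hb$dw
    g[[sprintf("%s_head_b", dname)]] <- hb$db
    dcur <- hb$dx
    for (i in seq_len(depth)) {
      cc <- cache[[sprintf("%s_dec%d", dname, i)]]
      d2 <- relu_backward(dcur, cc$r2)
      cb2 <- conv3_backward(d2, cc$c2, p[[sprintf("%s_dec%d_conv2_w", dname, i)]])
      g[[sprintf("%s_dec%d_conv2_w", dname, i)]] <- cb2$dw
      g[[sprintf("%s_dec%d_conv2_b", dname, i)]] <- cb2$db
      dd <- dropout_backward(cb2$dx, cc$dr)
      d1 <- relu_backward(dd, cc$r1)
      cb1 <- conv3_backward(d1, cc$c1, p[[sprintf("%s_dec%d_conv1_w", dname, i)]])
      g[[sprintf("%s_dec%d_conv1_w", dname, i)]] <- cb1$dw
      g[[sprintf("%s_dec%d_conv1_b", dname, i)]] <- cb1$db
      n_up <- cc$n_up
      dup <- cb1$dx[, , seq_len(n_up), drop = FALSE]
      dskip <- cb1$dx[, , n_up + seq_len(dim(cb1$dx)[3L] - n_up), drop = FALSE]
      dskips[[i]] <- if (is.null(dskips[[i]])) dskip else dskips[[i]] + dskip
      ub <- convt2_backward(dup, cc$up, p[[sprintf("%s_up%d_w", dname, i)]])
      g[[sprintf("%s_up%d_w", dname, i)]] <- ub$dw
      g[[sprintf("%s_up%d_b", dname, i)]] <- ub$db
      dcur <- ub$dx
    }
    dbott <- if (is.null(dbott)) dcur else dbott + dcur
  }

  bc <- cache$bott
  d2 <- relu_backward(dbott, bc$r2)
  cb2 <- conv3_backward(d2, bc$c2, p$bott_conv2_w)
  g$bott_conv2_w <- cb2$dw; g$bott_conv2_b <- cb2$db
  dd <- dropout_backward(cb2$dx, bc$dr)
  d1 <- relu_backward(dd, bc$r1)
  cb1 <- conv3_backward(d1, bc$c1, p$bott_conv1_w)
  g$bott_conv1_w <- cb1$dw; g$bott_conv1_b <- cb1$db
  dcur <- cb1$dx

  for (i in rev(seq_len(depth))) {
    ec <- cache[[sprintf("enc%d", i)]]
    dpool <- maxpool2_backward(dcur, ec$pl)
    dskip_total <- dpool + dskips[[i]]
    d2 <- relu_backward(dskip_total, ec$r2)
    cb2 <- conv3_backward(d2, ec$c2, p[[sprintf("enc%d_conv2_w", i)]])
    g[[sprintf("enc%d_conv2_w", i)]] <- cb2$dw
    g[[sprintf("enc%d_conv2_b", i)]] <- cb2$db
    dd <- dropout_backward(cb2$dx, ec$dr)
    d1 <- relu_backward(dd, ec$r1)
    cb1 <- conv3_backward(d1, ec$c1, p[[sprintf("enc%d_conv1_w", i)]])
    g[[sprintf("enc%d_conv1_w", i)]] <- cb1$dw
    g[[sprintf("enc%d_conv1_b", i)]] <- cb1$db
    dcur <- cb1$dx
  }
  g
}

#' Predict maps for a single image
#'
#' Runs the network in inference mode (dropout off). For a dual model the
#' result holds `distance` and `foreground_prob` maps; for a classifier a
#' `class_probs` array with per-pixel softmax probabilities.
#'
#' @param object A `nucseg_net`.
#' @param image H x W x 3 array of intensities in `[0, 1]`, sides multiples
#'   of the network stride.
#' @param tta Apply test-time augmentation (see [predict_with_tta()]).
#' @param ... Unused.
#' @export
predict.nucseg_net <- function(object, image, tta = FALSE, ...) {
  predict_with_tta(object, image, tta = tta)
}

clamp_prob <- function(p, eps = 1e-7) pmin(pmax(p, eps), 1 - eps)

soft_dice_loss <- function(p, g, eps = 1) {
  1 - (2 * sum(p * g) + eps) / (sum(p) + sum(g) + eps)
}

#' Composite loss of the dual-decoder model
#'
#' Unweighted sum of three terms: mean squared error between predicted and
#' target distance maps, soft Dice loss of the foreground probabilities
#' against the refined binary mask (smoothing constant `eps`), and mean
#' binary cross-entropy with probabilities clamped to `[1e-7, 1 - 1e-7]`.
#'
#' @param out List with `distance` and `foreground_prob` maps (as returned by
#'   the dual network).
#' @param gt_distance Target distance map in `[0, 1]`.
#' @param gt_binary Refined binary mask with values in `{0, 1}`.
#' @param eps Dice smoothing constant (default 1).
#' @return Scalar loss with attribute `components` (mse, dice, bce).
#' @export
dual_loss <- function(out, gt_distance, gt_binary, eps = 1) {
  if (!identical(dim(out$distance), dim(gt_distance)) ||
      !identical(dim(out$foreground_prob), dim(gt_binary)))
    stop("prediction and target shapes must match")
  mse <- mean((out$distance - gt_distance)^2)
  p <- clamp_prob(out$foreground_prob)
  bce <- -mean(gt_binary * log(p) + (1 - gt_binary) * log(1 - p))
  dice <- soft_dice_loss(out$foreground_prob, gt_binary, eps)
  structure(mse + dice + bce,
            components = c(mse = mse, dice = dice, bce = bce))
}

#' Loss of the classification model
#'
#' Mean categorical cross-entropy over pixels plus the mean over channels of
#' the per-channel soft Dice loss, unweighted.
#'
#' @param out List with a `class_probs` H x W x (K+1) array.
#' @param gt_onehot One-hot H x W x (K+1) target array (channel 1 is
#'   background).
#' @param eps Dice smoothing constant.
#' @export
class_loss <- function(out, gt_onehot, eps = 1) {
  pr <- out$class_probs
  if (!identical(dim(pr), dim(gt_onehot)))
    stop("prediction and target shapes must match")
  sums <- rowSums(matrix(gt_onehot, prod(dim(pr)[1:2]), dim(pr)[3L]))
  if (any(abs(sums - 1) > 1e-8) || any(gt_onehot != 0 & gt_onehot != 1))
    stop("gt_onehot must be one-hot at every pixel")
  n_pix <- prod(dim(pr)[1:2])
  cce <- -sum(gt_onehot * log(clamp_prob(pr))) / n_pix
  k1 <- dim(pr)[3L]
  dice <- mean(vapply(seq_len(k1), function(c)
    soft_dice_loss(pr[, , c], gt_onehot[, , c], eps), 0))
  structure(cce + dice, components = c(cce = cce, dice = dice))
}

# Loss plus gradients with respect to the head pre-activations, for training.
dual_loss_grad <- function(out, gt_distance, gt_binary, eps = 1) {
  n <- length(gt_distance)
  loss <- dual_loss(out, gt_distance, gt_binary, eps)
  d_dist <- 2 * (out$distance - gt_distance) / n
  p <- out$foreground_prob
  # BCE through the sigmoid collapses to (p - g)/n
  dz_bce <- (p - gt_binary) / n
  s <- sum(p) + sum(gt_binary) + eps
  tt <- 2 * sum(p * gt_binary) + eps
  dp_dice <- (tt - 2 * gt_binary * s) / s^2
  dz_dice <- dp_dice * p * (1 - p)
  list(loss = as.numeric(loss), components = attr(loss, "components"),
       head_grads = list(dist = d_dist, bin = dz_bce + dz_dice))
}

class_loss_grad <- function(out, gt_onehot, eps = 1) {
  loss <- class_loss(out, gt_onehot, eps)
  pr <- out$class_probs
  d <- dim(pr)
  n_pix <- prod(d[1:2]); k1 <- d[3L]
  dz_cce <- (pr - gt_onehot) / n_pix
  dp <- array(0, d)
  for (c in seq_len(k1)) {
    s <- sum(pr[, , c]) + sum(gt_onehot[, , c]) + eps
    tt <- 2 * sum(pr[, , c] * gt_onehot[, , c]) + eps
    dp[, , c] <- (tt - 2 * gt_onehot[, , c] * s) / s^2 / k1
  }
  # softmax Jacobian: dz = p * (dp - sum_c dp_c p_c)
  inner <- rowSums(matrix(dp * pr, n_pix, k1))
  dz_dice <- pr * (dp - as.vector(inner))
  list(loss = as.numeric(loss), components = attr(loss, "components"),
       head_grads = list(cls = dz_cce + dz_dice))
}
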