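# Layer primitives for the U-Net family implemented directly in R.
# Feature maps are H x W x C double arrays. Convolutions are evaluated as
# im2col gathers followed by BLAS matrix products; every layer returns the
# cache its analytic backward pass needs. 3x3 convolution weights are stored
# as (9*Cin) x Cout matrices whose rows are ordered channel-major, i.e. row
# (c-1)*9 + o corresponds to input channel c and kernel offset o, with
# o - 1 = (dr + 1) + 3*(dc + 1) for dr, dc in {-1, 0, 1}.

conv3_forward <- function(x, w, b) {
  d <- dim(x); h <- d[1L]; wd <- d[2L]
  col <- .im2col3(x, h, wd, d[3L])
  y <- col %*% w
  y <- y + rep(b, each = h * wd)
  dim(y) <- c(h, wd, length(b))
  list(out = y, col = col, xdim = d)
}

conv3_backward <- function(dy, cache, w) {
  d <- cache$xdim; h <- d[1L]; wd <- d[2L]
  dim(dy) <- c(h * wd, ncol(w))
  dw <- crossprod(cache$col, dy)
  db <- colSums(dy)
  dcol <- tcrossprod(dy, w)
  list(dx = .col2im3(dcol, h, wd, d[3L]), dw = dw, db = db)
}

relu_forward <- function(x) {
  mask <- x > 0
  x[!mask] <- 0
  list(out = x, mask = mask)
}

relu_backward <- function(dy, cache) {
  dy[!cache$mask] <- 0
  dy
}

# Inverted dropout; the mask already carries the 1/(1-rate) scale.
dropout_forward <- function(x, rate, training) {
  if (!training || rate <= 0) return(list(out = x, mask = NULL))
  mask <- array((stats::runif(length(x)) >= rate) / (1 - rate), dim(x))
  list(out = x * mask, mask = mask)
}

dropout_backward <- function(dy, cache) {
  if (is.null(cache$mask)) return(dy)
  dy * cache$mask
}

maxpool2_forward <- function(x) {
  d <- dim(x); h <- d[1L]; wd <- d[2L]
  r1 <- seq.int(1L, h, 2L); c1 <- seq.int(1L, wd, 2L)
  a <- x[r1, c1, , drop = FALSE]
  b <- x[r1 + 1L, c1, , drop = FALSE]
  cc <- x[r1, c1 + 1L, , drop = FALSE]
  dd <- x[r1 + 1L, c1 + 1L, , drop = FALSE]
  m <- pmax(a, b, cc, dd)
  # route each gradient to exactly one argmax pixel (first in a,b,cc,dd order)
  ma <- a == m
  mb <- (b == m) & !ma
  mc <- (cc == m) & !(ma | mb)
  md <- !(ma | mb | mc)
  list(out = m, masks = list(ma, mb, mc, md), xdim = d)
}

maxpool2_backward <- function(dy, cache) {
  d <- cache$xdim; h <- d[1L]; wd <- d[2L]
  r1 <- seq.int(1L, h, 2L); c1 <- seq.int(1L, wd, 2L)
  dx <- array(0, d)
  m <- cache$masks
  dx[r1, c1, ] <- dy * m[[1L]]
  dx[r1 + 1L, c1, ] <- dy * m[[2L]]
  dx[r1, c1 + 1L, ] <- dy * m[[3L]]
  dx[r1 + 1L, c1 + 1L, ] <- dy * m[[4L]]
  dx
}

# 2x2 stride-2 transposed convolution; weights are a (2, 2, Cin, Cout) array.
# With stride equal to kernel size every output pixel receives exactly one
# contribution, so forward and backward are four strided matrix products.
convt2_forward <- function(x, w, b) {
  d <- dim(x); h <- d[1L]; wd <- d[2L]; cin <- d[3L]
  cout <- dim(w)[4L]
  xm <- matrix(x, h * wd, cin)
  y <- array(0, c(2L * h, 2L * wd, cout))
  for (a in 1:2) for (bb in 1:2) {
    wab <- matrix(w[a, bb, , ], cin, cout)
    y[seq.int(a, 2L * h, 2L), seq.int(bb, 2L * wd, 2L), ] <-
      array(xm %*% wab, c(h, wd, cout))
  }
  y <- y + rep(b, each = 4L * h * wd)
  list(out = y, xm = xm, xdim = d)
}

convt2_backward <- function(dy, cache, w) {
  d <- cache$xdim; h <- d[1L]; wd <- d[2L]; cin <- d[3L]
  cout <- dim(w)[4L]
  dw <- array(0, dim(w))
  dxm <- matrix(0, h * wd, cin)
  for (a in 1:2) for (bb in 1:2) {
    dyp <- matrix(dy[seq.int(a, 2L * h, 2L), seq.int(bb, 2L * wd, 2L), ,
                     drop = FALSE], h * wd, cout)
    dw[a, bb, , ] <- crossprod(cache$xm, dyp)
    dxm <- dxm + tcrossprod(dyp, matrix(w[a, bb, , ], cin, cout))
  }
  db <- colSums(matrix(dy, 4L * h * wd, cout))
  list(dx = array(dxm, d), dw = dw, db = db)
}

# 1x1 convolution head.
conv1_forward <- function(x, w, b) {
  d <- dim(x); h <- d[1L]; wd <- d[2L]
  xm <- matrix(x, h * wd, d[3L])
  y <- xm %*% w + rep(b, each = h * wd)
  list(out = array(y, c(h, wd, ncol(w))), xm = xm, xdim = d)
}

conv1_backward <- function(dy, cache, w) {
  d <- cache$xdim
  dym <- matrix(dy, d[1L] * d[2L], ncol(w))
  list(dx = array(tcrossprod(dym, w), d),
       dw = crossprod(cache$xm, dym), db = colSums(dym))
}

concat_channels <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1L], da[2L], da[3L] + db[3L]))
  out[, , seq_len(da[3L])] <- a
  out[, , da[3L] + seq_len(db[3L])] <- b
  out
}

sigmoid <- function(z) 1 / (1 + exp(-z))

softmax_channels <- function(z) {
  m <- apply(z, c(1L, 2L), max)
  e <- exp(z - as.vector(m))
  e / as.vector(rowSums(matrix(e, length(m), dim(z)[3L])))
}
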