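# Raster I/O. Images travel as 8-bit RGB PNG, instance label masks as 16-bit
# single-channel TIFF (0 = background, k = instance k), class masks as 8-bit
# single-channel PNG. All in-memory representations are H x W(, C) arrays in
# row/column order; png/tiff store row-major, matching R's matrix layout as
# used by both packages (first dim = image rows).

#' Write / read an RGB image as 8-bit PNG
#'
#' @param image H x W x 3 array of intensities in `[0, 1]`.
#' @param path File path.
#' @export
write_image_png <- function(image, path) {
  stopifnot(length(dim(image)) == 3L)
  png::writePNG(pmin(pmax(image, 0), 1), path)
  invisible(path)
}

#' @rdname write_image_png
#' @export
read_image_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 2L) img <- array(rep(img, 3L), c(dim(img), 3L))
  img[, , 1:3, drop = FALSE]
}

#' Write / read an instance label mask as 16-bit TIFF
#'
#' Labels up to 65535 are stored losslessly.
#' @param labels Integer matrix, 0 = background.
#' @param path File path.
#' @export
write_label_mask <- function(labels, path) {
  if (max(labels) > 65535L) stop("label mask exceeds 16-bit range")
  tiff::writeTIFF(labels / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_label_mask
#' @export
read_label_mask <- function(path) {
  m <- tiff::readTIFF(path)
  if (length(dim(m)) == 3L) m <- m[, , 1L]
  matrix(as.integer(round(m * 65535)), nrow(m), ncol(m))
}

#' Write / read a class mask as 8-bit PNG
#'
#' @param classes Integer matrix of class codes 0..255.
#' @param path File path.
#' @export
write_class_mask <- function(classes, path) {
  if (max(classes) > 255L) stop("class mask exceeds 8-bit range")
  png::writePNG(classes / 255, path)
  invisible(path)
}

#' @rdname write_class_mask
#' @export
read_class_mask <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3L) m <- m[, , 1L]
  matrix(as.integer(round(m * 255)), nrow(m), ncol(m))
}

# Model checkpoints: the parameter list plus architecture config, written
# with saveRDS. The config is embedded so fine-tuning can verify
# compatibility.
save_checkpoint <- function(net, path) {
  saveRDS(list(config = net$config, type = net$type, params = net$params,
               init_seed = net$init_seed), path)
  invisible(path)
}

load_checkpoint <- function(path) {
  x <- readRDS(path)
  structure(list(config = x$config, type = x$type, params = x$params,
                 init_seed = x$init_seed), class = "nucseg_net")
}
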