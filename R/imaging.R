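#' Jet colormap lookup table
#'
#' Classic piecewise-linear jet colormap (dark blue through cyan, yellow
#' and red), as used for rendering scalograms into RGB images.
#'
#' @param n Number of colour levels.
#' @return An `n x 3` numeric matrix of RGB values in `[0, 1]`, row 1 the
#'   lowest (dark blue) entry.
#' @export
jet_colormap <- function(n = 256) {
  stopifnot(is.numeric(n), length(n) == 1L, n >= 1, n == round(n))
  n <- as.integer(n)
  q <- as.integer(ceiling(n / 4))
  u <- c(seq_len(q) / q, rep(1, max(q - 1L, 0L)), seq(q, 1) / q)
  g0 <- as.integer(ceiling(q / 2)) - as.integer(n %% 4 == 1)
  g <- g0 + seq_along(u)
  r <- g + q
  b <- g - q
  lut <- matrix(0, nrow = n, ncol = 3)
  ok <- function(ix) ix >= 1L & ix <= n
  lut[r[ok(r)], 1] <- u[ok(r)]
  lut[g[ok(g)], 2] <- u[ok(g)]
  lut[b[ok(b)], 3] <- u[ok(b)]
  colnames(lut) <- c("red", "green", "blue")
  lut
}

# Bilinear interpolation weight matrix mapping `n_in` source pixels to
# `n_out` target pixels (pixel centers aligned, edges clamped).
bilinear_weights <- function(n_out, n_in) {
  if (n_in == 1L) return(matrix(1, nrow = n_out, ncol = 1))
  pos <- ((seq_len(n_out) - 0.5) * n_in / n_out) - 0.5
  pos <- pmin(pmax(pos, 0), n_in - 1)
  lo <- floor(pos)
  frac <- pos - lo
  hi <- pmin(lo + 1, n_in - 1)
  w <- matrix(0, nrow = n_out, ncol = n_in)
  w[cbind(seq_len(n_out), lo + 1)] <- 1 - frac
  w[cbind(seq_len(n_out), hi + 1)] <- w[cbind(seq_len(n_out), hi + 1)] + frac
  w
}

#' Render a scalogram magnitude matrix as a fixed-size RGB image
#'
#' The linear magnitude is min-max rescaled to `[0, 1]` per image,
#' quantized into `levels` bins, mapped through a jet colour lookup table,
#' and resized to the target size with bilinear interpolation.  Scalogram
#' rows are in descending frequency, so frequency increases upward in the
#' rendered image (row 1 is the top).  A zero-dynamic-range (constant)
#' matrix maps uniformly to the lowest colormap entry; it is not an error.
#'
#' @param x An `ecg_scalogram` or a nonnegative magnitude matrix.
#' @param size Target `c(height, width)` in pixels.  Default `c(227, 227)`,
#'   the AlexNet input convention; use `c(224, 224)` for the ResNet
#'   convention.
#' @param levels Number of colormap quantization levels. Default 128.
#' @param source_id Provenance string carried on the image.
#'
#' @return An object of class `ecg_rgb_image`: a list with `pixels`
#'   (H x W x 3 integer array, values in 0..255), `height`, `width` and
#'   `source_id`.
#' @examples
#' img <- scalogram_to_image(matrix(runif(50 * 40), 50), size = c(64, 64))
#' dim(img$pixels)
#' @export
scalogram_to_image <- function(x, size = c(227, 227), levels = 128,
                               source_id = "") {
  if (inherits(x, "ecg_scalogram")) {
    mag <- scalogram_magnitude(x)
  } else if (is.matrix(x) && is.numeric(x)) {
    mag <- x
  } else {
    stop("`x` must be an `ecg_scalogram` or a numeric matrix")
  }
  if (length(mag) == 0L) stop("magnitude matrix is empty")
  if (anyNA(mag) || any(!is.finite(mag))) {
    stop("magnitude matrix contains non-finite values")
  }
  stopifnot(length(size) == 2L, all(size >= 1), all(size == round(size)),
            is.numeric(levels), levels >= 2, levels == round(levels))
  size <- as.integer(size)
  levels <- as.integer(levels)

  rng <- max(mag) - min(mag)
  if (rng == 0) {
    idx <- matrix(1L, nrow(mag), ncol(mag))
  } else {
    u <- (mag - min(mag)) / rng
    idx <- pmin(floor(u * levels) + 1L, levels)
  }
  lut <- jet_colormap(levels)

  a <- bilinear_weights(size[1], nrow(mag))
  b <- bilinear_weights(size[2], ncol(mag))
  pixels <- array(0L, dim = c(size[1], size[2], 3L))
  for (ch in 1:3) {
    plane <- matrix(lut[idx, ch], nrow = nrow(mag))
    res <- a %*% plane %*% t(b)
    pixels[, , ch] <- as.integer(pmin(pmax(round(res * 255), 0), 255))
  }
  structure(
    list(pixels = pixels, height = size[1], width = size[2],
         source_id = source_id),
    class = "ecg_rgb_image"
  )
}

#' @export
print.ecg_rgb_image <- function(x, ...) {
  cat(sprintf("RGB image %d x %d%s\n", x$height, x$width,
              if (nzchar(x$source_id)) paste0(" [", x$source_id, "]") else ""))
  invisible(x)
}

#' Write an RGB image to a PNG file
#'
#' @param image An `ecg_rgb_image`.
#' @param path Output path (PNG).
#' @return Invisibly, `path`.
#' @export
write_image <- function(image, path) {
  stopifnot(inherits(image, "ecg_rgb_image"))
  if (!dir.exists(dirname(path))) {
    stop("cannot write image: directory does not exist: ", dirname(path))
  }
  png::writePNG(image$pixels / 255, path)
  invisible(path)
}

#' Read an RGB image from a PNG file
#'
#' 8-bit PNGs round-trip losslessly through [write_image()] /
#' `read_image()`.
#'
#' @param path Path to a PNG file.
#' @return An `ecg_rgb_image`.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("image file does not exist: ", path)
  px <- png::readPNG(path)
  if (length(dim(px)) == 2L) px <- array(rep(px, 3), dim = c(dim(px), 3L))
  if (dim(px)[3] > 3L) px <- px[, , 1:3, drop = FALSE]
  pixels <- array(as.integer(round(px * 255)), dim = dim(px))
  structure(
    list(pixels = pixels, height = dim(px)[1], width = dim(px)[2],
         source_id = path),
    class = "ecg_rgb_image"
  )
}

#' Plot an RGB image
#'
#' @param object An `ecg_rgb_image`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ecg_rgb_image
#' @export
autoplot.ecg_rgb_image <- function(object, ...) {
  px <- object$pixels
  df <- expand.grid(row = seq_len(object$height), col = seq_len(object$width))
  df$colour <- grDevices::rgb(px[, , 1] / 255, px[, , 2] / 255, px[, , 3] / 255)
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row)) +
    ggplot2::geom_raster(fill = df$colour) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::theme_void()
}
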