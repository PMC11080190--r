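#' Read an image file into an intensity array
#'
#' Images are represented throughout the package as numeric arrays of
#' dimension height x width x 3 with intensities in `[0, 1]`. PNG is read
#' natively; grayscale and alpha channels are normalized to plain RGB.
#'
#' @param path Path to a PNG file.
#' @return Numeric array `h x w x 3` in `[0, 1]`.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("image file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext != "png") {
    stop("unsupported image format '", ext, "' (PNG expected): ", path)
  }
  img <- png::readPNG(path)
  as_rgb_array(img)
}

#' @rdname read_image
#' @param img Image array (values clamped to `[0, 1]` on write).
#' @export
write_image <- function(img, path) {
  img <- pmin(pmax(img, 0), 1)
  png::writePNG(img, path)
  invisible(path)
}

as_rgb_array <- function(img) {
  if (length(dim(img)) == 2) {
    img <- array(rep(img, 3), dim = c(dim(img), 3))
  } else if (dim(img)[3] == 4) {
    img <- img[, , 1:3, drop = FALSE]
  } else if (dim(img)[3] == 1) {
    img <- array(rep(img[, , 1], 3), dim = c(dim(img)[1:2], 3))
  }
  storage.mode(img) <- "double"
  img
}

# Bilinear sampling of img at fractional (row, col) coordinates; coordinates
# outside the image return `fill`. xr/xc are equal-length vectors.
bilinear_sample <- function(img, xr, xc, fill = 0) {
  h <- dim(img)[1]
  w <- dim(img)[2]
  nc <- dim(img)[3]
  r0 <- floor(xr)
  c0 <- floor(xc)
  fr <- xr - r0
  fc <- xc - c0
  out <- matrix(fill, nrow = length(xr), ncol = nc)
  # corner contribution helper: accumulate weight * pixel for in-bounds taps
  for (corner in 1:4) {
    rr <- r0 + (corner == 2 | corner == 4)
    cc <- c0 + (corner == 3 | corner == 4)
    wgt <- switch(corner,
      (1 - fr) * (1 - fc),
      fr * (1 - fc),
      (1 - fr) * fc,
      fr * fc
    )
    ok <- rr >= 1 & rr <= h & cc >= 1 & cc <= w
    if (!any(ok)) next
    idx <- rr[ok] + (cc[ok] - 1) * h
    for (ch in seq_len(nc)) {
      plane <- img[, , ch]
      out[ok, ch] <- out[ok, ch] + wgt[ok] * plane[idx]
    }
    # out-of-bounds taps implicitly contribute `fill`
    if (any(!ok)) {
      for (ch in seq_len(nc)) {
        out[!ok, ch] <- out[!ok, ch] + wgt[!ok] * fill
      }
    }
  }
  out
}

# Warp an image with an inverse map: for each output pixel (r, c) the
# function `inv` returns source (row, col) coordinates in the input image.
# Used for rotation, affine and perspective transforms.
warp_image <- function(img, inv, out_h, out_w, fill = 0) {
  grid_r <- rep(seq_len(out_h), times = out_w)
  grid_c <- rep(seq_len(out_w), each = out_h)
  src <- inv(grid_r, grid_c)
  vals <- bilinear_sample(img, src[[1]], src[[2]], fill = fill)
  array(vals, dim = c(out_h, out_w, dim(img)[3]))
}
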