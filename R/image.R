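#' Grayscale image with physical pixel spacing
#'
#' Container for a 2-D nonnegative intensity grid. Row index `i` counts pixels
#' down from the top edge, column index `j` pixels right from the left edge
#' (matrix convention). Pixel spacing is physical, in mm per pixel, and may be
#' anisotropic (AS-OCT instruments typically sample the axial direction more
#' coarsely than the lateral one).
#'
#' @param pixels numeric matrix of finite, nonnegative intensities.
#' @param px_mm_x horizontal pixel spacing, mm/px.
#' @param px_mm_y vertical pixel spacing, mm/px.
#' @return An object of class `gray_image`: a list with elements `pixels`,
#'   `px_mm_x`, `px_mm_y`.
#' @export
gray_image <- function(pixels, px_mm_x, px_mm_y) {
  pixels <- as.matrix(pixels)
  if (!is.numeric(pixels) || length(dim(pixels)) != 2L)
    stop("`pixels` must be a numeric matrix")
  if (any(!is.finite(pixels)))
    stop("image intensities must be finite")
  if (any(pixels < 0))
    stop("image intensities must be nonnegative")
  if (!is.numeric(px_mm_x) || !is.numeric(px_mm_y) ||
      px_mm_x <= 0 || px_mm_y <= 0)
    stop("pixel spacings must be positive")
  storage.mode(pixels) <- "double"
  structure(
    list(pixels = pixels, px_mm_x = as.numeric(px_mm_x),
         px_mm_y = as.numeric(px_mm_y)),
    class = "gray_image"
  )
}

#' @export
print.gray_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf(
    "<gray_image> %d x %d px (%.4g x %.4g mm), range [%.3g, %.3g]\n",
    d[1], d[2], d[1] * x$px_mm_y, d[2] * x$px_mm_x,
    min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' @export
dim.gray_image <- function(x) dim(x$pixels)

is_gray_image <- function(x) inherits(x, "gray_image")

as_pixels <- function(img) {
  if (is_gray_image(img)) img$pixels
  else if (inherits(img, "aligned_image")) img$canvas
  else as.matrix(img)
}

#' Read a grayscale image from PNG or TIFF
#'
#' Multi-channel files are collapsed to grayscale by averaging channels.
#' Pixel spacing is not stored in these formats and must be supplied.
#'
#' @param path file path ending in .png, .tif or .tiff.
#' @param px_mm_x,px_mm_y pixel spacing in mm/px.
#' @return A [gray_image].
#' @export
read_gray_image <- function(path, px_mm_x, px_mm_y) {
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png  = png::readPNG(path),
    tif  = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format: ", ext)
  )
  if (length(dim(arr)) == 3L) arr <- rowMeans(arr, dims = 2L)
  gray_image(arr, px_mm_x, px_mm_y)
}

#' Write a grayscale image to PNG (8-bit) or TIFF (16-bit)
#'
#' Intensities are clipped to \[0, 1\] before writing.
#'
#' @param img a [gray_image] or plain matrix.
#' @param path destination; extension selects the format.
#' @export
write_gray_image <- function(img, path) {
  m <- pmin(pmax(as_pixels(img), 0), 1)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png  = png::writePNG(m, path),
    tif  = ,
    tiff = tiff::writeTIFF(m, path, bits.per.sample = 16L),
    stop("unsupported image format: ", ext)
  )
  invisible(path)
}

# ---- resampling utilities ---------------------------------------------------

# Bilinear sample of matrix `m` at fractional 0-based coordinates (si, sj)
# (vectors of equal length). Points outside the grid return `fill`.
bilinear_sample <- function(m, si, sj, fill = 0) {
  nr <- nrow(m); nc <- ncol(m)
  i0 <- floor(si); j0 <- floor(sj)
  fi <- si - i0;   fj <- sj - j0
  out <- rep(fill, length(si))
  # a corner contributes when its integer coords are inside the grid
  acc <- numeric(length(si))
  wsum <- numeric(length(si))
  for (corner in list(c(0, 0), c(0, 1), c(1, 0), c(1, 1))) {
    ii <- i0 + corner[1]; jj <- j0 + corner[2]
    w <- (if (corner[1] == 0) 1 - fi else fi) *
         (if (corner[2] == 0) 1 - fj else fj)
    ok <- ii >= 0 & ii <= nr - 1 & jj >= 0 & jj <= nc - 1
    idx <- ii[ok] + 1L + jj[ok] * nr
    acc[ok] <- acc[ok] + w[ok] * m[idx]
    wsum[ok] <- wsum[ok] + w[ok]
  }
  # pixels with all four corners outside stay at `fill`; partial coverage is
  # renormalized so edges are not darkened by the zero exterior
  inside <- wsum > 0
  out[inside] <- acc[inside] / wsum[inside]
  out
}

# Backward-gather affine resampling. For each output pixel q (0-based (i,j)),
# samples the source at p = R_b %*% (q - center_out) + center_src, bilinear,
# zero fill. R_b is the backward (output -> source) 2x2 matrix acting on
# (i, j) column vectors. A single gather composes rotation and translation so
# the image is interpolated only once.
warp_gather <- function(src, out_dim, R_b, center_out, center_src) {
  nr <- out_dim[1]; nc <- out_dim[2]
  qi <- rep(0:(nr - 1), times = nc) - center_out[1]
  qj <- rep(0:(nc - 1), each = nr) - center_out[2]
  si <- R_b[1, 1] * qi + R_b[1, 2] * qj + center_src[1]
  sj <- R_b[2, 1] * qi + R_b[2, 2] * qj + center_src[2]
  matrix(bilinear_sample(src, si, sj), nr, nc)
}

# Rotation matrix (in the (i, j) basis) by `deg` degrees; positive angles
# rotate the +j (rightward) axis toward +i (downward).
rot2 <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
}

# Shared pose warp: rotation by `deg` about the physical image center (in the
# mm frame, so anisotropic pixels still see a rigid rotation) followed by an
# integer pixel translation (di, dj); one bilinear backward gather, zero fill.
warp_pose_matrix <- function(m, px_mm_x, px_mm_y, deg, shift_px = c(0L, 0L)) {
  if (deg == 0 && all(shift_px == 0)) return(m)
  nr <- nrow(m); nc <- ncol(m)
  S <- diag(c(px_mm_y, px_mm_x))                # (i, j) -> (y, x) scaling
  R_b <- solve(S) %*% rot2(-deg) %*% S
  ctr <- c((nr - 1) / 2, (nc - 1) / 2)
  warp_gather(m, c(nr, nc), R_b,
              center_out = ctr + shift_px, center_src = ctr)
}

#' Rigidly transform an image in-plane
#'
#' Rotates the image by `rotation_deg` about its physical center (the
#' rotation is rigid in millimetre coordinates even when the pixel grid is
#' anisotropic) and then translates it by an integer number of pixels, in a
#' single bilinear resampling with zero fill. Useful for constructing posed
#' copies of an image, e.g. to probe the pose invariance of [align()].
#'
#' @param img a [gray_image].
#' @param rotation_deg in-plane rotation, degrees.
#' @param shift_px integer translation `c(di, dj)` (down, right).
#' @return The transformed [gray_image] (same size and spacing).
#' @export
transform_image <- function(img, rotation_deg = 0, shift_px = c(0L, 0L)) {
  stopifnot(is_gray_image(img))
  m <- warp_pose_matrix(img$pixels, img$px_mm_x, img$px_mm_y,
                        rotation_deg, round(shift_px))
  gray_image(pmax(m, 0), img$px_mm_x, img$px_mm_y)
}

# Linear 1-D resize of each column (axis = "rows") or row (axis = "cols")
# from n_in to n_out samples, preserving physical extent: sample positions are
# chosen so that pixel 0 maps to pixel 0 and the last pixel to the last pixel.
resize_axis_linear <- function(m, n_out, axis = c("rows", "cols")) {
  axis <- match.arg(axis)
  if (axis == "cols") return(t(resize_axis_linear(t(m), n_out, "rows")))
  n_in <- nrow(m)
  if (n_out == n_in) return(m)
  pos <- if (n_out == 1L) 0 else seq(0, n_in - 1, length.out = n_out)
  i0 <- pmin(floor(pos), n_in - 2L)
  f <- pos - i0
  m[i0 + 1L, , drop = FALSE] * (1 - f) + m[i0 + 2L, , drop = FALSE] * f
}
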