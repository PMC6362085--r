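#' Linearly rescale intensities to \[0, 1\]
#'
#' Affine map `(x - min) / (max - min)` so that the darkest pixel becomes 0
#' and the brightest 1. A constant image has zero dynamic range and is
#' rejected.
#'
#' @param img a [gray_image].
#' @return A [gray_image] with the same geometry, intensities in \[0, 1\].
#' @export
normalize_intensity <- function(img) {
  stopifnot(is_gray_image(img))
  m <- img$pixels
  rng <- range(m)
  if (rng[1] == rng[2])
    stop("constant image: zero dynamic range, cannot normalize")
  gray_image((m - rng[1]) / (rng[2] - rng[1]), img$px_mm_x, img$px_mm_y)
}

#' Make the pixel spacing isotropic
#'
#' AS-OCT rasters are anisotropic (a typical instrument samples 16 mm
#' laterally over 1024 px but 8 mm axially over only 256 px). The coarser axis
#' is upsampled by linear interpolation to the finer spacing, preserving
#' detail on the finer axis; the physical extent is preserved to within one
#' pixel.
#'
#' @param img a [gray_image].
#' @return A [gray_image] with `px_mm_x == px_mm_y == min(input spacings)`.
#' @export
homogenize_resolution <- function(img) {
  stopifnot(is_gray_image(img))
  if (img$px_mm_x <= 0 || img$px_mm_y <= 0)
    stop("pixel spacings must be positive")
  if (img$px_mm_x == img$px_mm_y) return(img)
  target <- min(img$px_mm_x, img$px_mm_y)
  m <- img$pixels
  if (img$px_mm_y > target) {      # rows are coarse: upsample vertically
    n_out <- max(2L, as.integer(round(nrow(m) * img$px_mm_y / target)))
    m <- resize_axis_linear(m, n_out, "rows")
  } else {                         # columns are coarse: upsample horizontally
    n_out <- max(2L, as.integer(round(ncol(m) * img$px_mm_x / target)))
    m <- resize_axis_linear(m, n_out, "cols")
  }
  gray_image(m, target, target)
}

#' Rectangular median filter with a window given in millimetres
#'
#' Applies a 2-D rectangular median filter whose window is specified in
#' physical units and converted to the nearest odd pixel count per axis
#' (at least 1). The default window of 0.055 mm x 0.117 mm (height x width)
#' counteracts the directional spreading of noise introduced by resolution
#' homogenization. Borders are handled by edge replication. A window that
#' converts to a single pixel in both axes degrades to the identity with a
#' warning.
#'
#' @param img an isotropic [gray_image].
#' @param window_mm numeric length-2, window `c(height_mm, width_mm)`.
#' @return The filtered [gray_image].
#' @export
median_filter_mm <- function(img, window_mm = c(0.055, 0.117)) {
  stopifnot(is_gray_image(img))
  if (img$px_mm_x != img$px_mm_y)
    stop("median_filter_mm expects an isotropic image; run homogenize_resolution first")
  px <- img$px_mm_x
  to_odd <- function(mm) {
    k <- max(1L, as.integer(round(mm / px)))
    if (k %% 2L == 0L) k + 1L else k
  }
  kh <- to_odd(window_mm[1]); kw <- to_odd(window_mm[2])
  if (kh == 1L && kw == 1L) {
    warning("median window smaller than one pixel; returning image unchanged")
    return(img)
  }
  gray_image(median_filter_rect(img$pixels, kh, kw), px, px)
}

#' Perona-Malik anisotropic diffusion
#'
#' Edge-preserving smoothing by the explicit Perona-Malik scheme with
#' 4-neighbor gradients and exponential conduction
#' `g(grad) = exp(-(grad / kappa)^2)`:
#' `u <- u + lam * (gN * dN + gS * dS + gE * dE + gW * dW)`.
#' Smooths away high spatial frequencies while retaining the strong edges
#' that delimit cornea, iris and lens. Stability of the explicit scheme
#' requires `lam <= 0.25`. The output range never exceeds the input range,
#' and constant images are fixed points.
#'
#' @param img a [gray_image].
#' @param n_iter number of iterations; 0 returns the input unchanged.
#' @param kappa edge scale (intensity units; default tuned for \[0, 1\]
#'   intensities).
#' @param lam integration step, in (0, 0.25\].
#' @return The diffused [gray_image].
#' @export
anisotropic_diffusion <- function(img, n_iter = 15L, kappa = 0.1, lam = 0.25) {
  stopifnot(is_gray_image(img))
  if (n_iter < 0) stop("n_iter must be nonnegative")
  if (lam <= 0 || lam > 0.25) stop("lam must be in (0, 0.25] for stability")
  if (kappa <= 0) stop("kappa must be positive")
  u <- img$pixels
  if (n_iter == 0L) return(img)
  nr <- nrow(u); nc <- ncol(u)
  g <- function(d) exp(-(d / kappa)^2)
  for (it in seq_len(n_iter)) {
    # replicated-edge neighbor differences (zero flux across the border)
    dN <- rbind(u[1, , drop = FALSE], u[-nr, , drop = FALSE]) - u
    dS <- rbind(u[-1, , drop = FALSE], u[nr, , drop = FALSE]) - u
    dW <- cbind(u[, 1, drop = FALSE], u[, -nc, drop = FALSE]) - u
    dE <- cbind(u[, -1, drop = FALSE], u[, nc, drop = FALSE]) - u
    u <- u + lam * (g(dN) * dN + g(dS) * dS + g(dE) * dE + g(dW) * dW)
  }
  gray_image(u, img$px_mm_x, img$px_mm_y)
}

#' Raw image moments, centroid and covariance
#'
#' Computes the six raw sums over the intensity-weighted pixel grid,
#' `S = sum M(i,j)`, `X = sum j M(i,j)`, `Y = sum i M(i,j)`,
#' `XX = sum j^2 M`, `YY = sum i^2 M`, `XY = sum i j M`, using 0-based pixel
#' indices (`i` down from the top edge, `j` right from the left edge), plus
#' the centroid `(Y/S, X/S)` and the 2 x 2 intensity covariance matrix
#' (row/col order `(i, j)`). The centroid and covariance drive the centering
#' and principal-axis alignment of [align()].
#'
#' @param img a [gray_image] or matrix with at least one nonzero pixel.
#' @return Object of class `image_moments`: list with `S`, `X`, `Y`, `XX`,
#'   `YY`, `XY`, `centroid` (i, j) and `cov`.
#' @export
compute_moments <- function(img) {
  m <- as_pixels(img)
  storage.mode(m) <- "double"
  S <- sum(m)
  if (S <= 0) stop("all-zero image: moments undefined (S = 0)")
  i <- 0:(nrow(m) - 1); j <- 0:(ncol(m) - 1)
  rs <- rowSums(m); cs <- colSums(m)
  Y  <- sum(i * rs);     X  <- sum(j * cs)
  YY <- sum(i^2 * rs);   XX <- sum(j^2 * cs)
  XY <- sum((i * m) %*% j)
  cov <- matrix(c(YY / S - (Y / S)^2, XY / S - (X / S) * (Y / S),
                  XY / S - (X / S) * (Y / S), XX / S - (X / S)^2), 2, 2)
  structure(list(S = S, X = X, Y = Y, XX = XX, YY = YY, XY = XY,
                 centroid = c(i = Y / S, j = X / S), cov = cov),
            class = "image_moments")
}

#' @export
print.image_moments <- function(x, ...) {
  cat(sprintf("<image_moments> S = %.6g, centroid = (%.3f, %.3f)\n",
              x$S, x$centroid[1], x$centroid[2]))
  invisible(x)
}

# Principal eigenvector of the moment covariance, under the sign convention
# that the horizontal (j) component is nonnegative (so alignment never flips
# images left-right); a purely vertical axis takes nonnegative i-component.
principal_axis <- function(cov, tol = 1e-12) {
  e <- eigen(cov, symmetric = TRUE)
  degenerate <- abs(e$values[1] - e$values[2]) <=
    tol * max(abs(e$values[1]), 1)
  v <- e$vectors[, 1]
  if (v[2] < 0 || (v[2] == 0 && v[1] < 0)) v <- -v
  list(v1 = v, degenerate = degenerate)
}

#' Center and principal-axis-align an image into a doubled canvas
#'
#' Computes the intensity centroid and covariance of the (isotropic) source
#' and resamples it, in a single bilinear affine gather, into a zero-
#' initialized canvas twice the source height and width, such that the
#' centroid lands on the canvas center and the principal eigenvector of the
#' covariance is horizontal. Canvas pixels not covered by the rotated source
#' remain exactly 0. This removes the in-plane pose (orientation, position)
#' of the eye, which otherwise dominates inter-image distances.
#'
#' If the two covariance eigenvalues coincide (rotationally symmetric mass),
#' the rotation is undefined; the identity rotation is applied with a
#' warning.
#'
#' @param img an isotropic, nonzero [gray_image].
#' @param source_id optional identifier carried into the result.
#' @return Object of class `aligned_image`: list with `canvas` (matrix),
#'   `px_mm`, `source_id`, `S` (source mass), `rotation_deg` (rotation that
#'   was applied) and `centroid` (source centroid, 0-based (i, j)).
#' @export
align <- function(img, source_id = NA_character_) {
  stopifnot(is_gray_image(img))
  if (img$px_mm_x != img$px_mm_y)
    stop("align expects an isotropic image; run homogenize_resolution first")
  mo <- compute_moments(img)
  pa <- principal_axis(mo$cov)
  if (pa$degenerate) {
    warning("covariance eigenvalues are equal: rotation undefined, applying identity")
    R_f <- diag(2)
    rot_deg <- 0
  } else {
    v <- pa$v1                       # (i, j) components, v[2] >= 0
    # forward rotation taking v1 to the horizontal axis (0, 1)
    R_f <- matrix(c(v[2], -v[1], v[1], v[2]), 2, 2, byrow = TRUE)
    rot_deg <- atan2(v[1], v[2]) * 180 / pi
  }
  nr <- nrow(img$pixels); nc <- ncol(img$pixels)
  out_dim <- c(2L * nr, 2L * nc)
  center_out <- (out_dim - 1) / 2
  canvas <- warp_gather(img$pixels, out_dim, t(R_f),
                        center_out = center_out, center_src = mo$centroid)
  structure(list(canvas = canvas, px_mm = img$px_mm_x,
                 source_id = source_id, S = mo$S,
                 rotation_deg = -rot_deg, centroid = mo$centroid),
            class = "aligned_image")
}

#' @export
print.aligned_image <- function(x, ...) {
  cat(sprintf("<aligned_image> %d x %d canvas, %.4g mm/px, S = %.5g, rotation %.2f deg\n",
              nrow(x$canvas), ncol(x$canvas), x$px_mm, x$S, x$rotation_deg))
  invisible(x)
}

#' Full pre-processing chain for one image
#'
#' Runs, in order: intensity normalization, resolution homogenization,
#' rectangular median filter, Perona-Malik anisotropic diffusion, and
#' centering/principal-axis alignment into the doubled canvas.
#'
#' @param img a [gray_image].
#' @param source_id identifier carried into the aligned result.
#' @param median_window_mm window of [median_filter_mm()].
#' @param diffusion_iter,diffusion_kappa,diffusion_lam parameters of
#'   [anisotropic_diffusion()].
#' @return An `aligned_image` (see [align()]).
#' @export
preprocess_image <- function(img, source_id = NA_character_,
                             median_window_mm = c(0.055, 0.117),
                             diffusion_iter = 15L, diffusion_kappa = 0.1,
                             diffusion_lam = 0.25) {
  img <- normalize_intensity(img)
  img <- homogenize_resolution(img)
  img <- suppressWarnings(median_filter_mm(img, median_window_mm))
  img <- anisotropic_diffusion(img, diffusion_iter, diffusion_kappa,
                               diffusion_lam)
  align(img, source_id = source_id)
}
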