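#' Direction in the (w, v) plane best correlated with a feature
#'
#' Finds the unit direction `u(theta)` maximizing the absolute Pearson
#' correlation between the projection `coords %*% u` and a per-image feature.
#' The maximum has a closed form: the optimal direction is proportional to
#' the least-squares coefficients of the centered feature on the centered
#' coordinates, and the maximal `|r|` equals the multiple correlation
#' coefficient `sqrt(R^2)` of that two-predictor fit. Images with missing
#' feature values are dropped pairwise.
#'
#' @param emb an `oct_embedding` (2-D).
#' @param feature numeric vector, one value per embedded image (NAs allowed).
#' @return Object of class `direction_correlation`: list with `theta`
#'   (radians, in `[0, pi)`), `r` (signed Pearson correlation of the
#'   projection at `theta`), `n` (images used) and `feature_name`.
#' @export
best_correlation_direction <- function(emb, feature,
                                       feature_name = deparse(substitute(feature))) {
  X <- emb$coords
  if (ncol(X) != 2L) stop("embedding must be two-dimensional")
  ok <- is.finite(feature)
  X <- X[ok, , drop = FALSE]; y <- feature[ok]
  n <- length(y)
  if (n < 3L) stop("need at least 3 images with feature values")
  if (sd(y) == 0) stop("feature is constant")
  Xc <- sweep(X, 2, colMeans(X))
  yc <- y - mean(y)
  # least squares via QR (better conditioned than the normal equations)
  beta <- tryCatch(qr.coef(qr(Xc), yc), error = function(e) NULL)
  if (is.null(beta) || any(!is.finite(beta))) {
    # degenerate (collinear) coordinates: fall back to the dominant axis
    v <- eigen(crossprod(Xc), symmetric = TRUE)$vectors[, 1]
    beta <- v * as.numeric(cor(Xc %*% v, yc))
  }
  u <- beta / sqrt(sum(beta^2))
  theta <- atan2(u[2], u[1]) %% pi
  u_theta <- c(cos(theta), sin(theta))
  r <- as.numeric(cor(X %*% u_theta, y))
  structure(list(theta = theta, r = r, n = n, feature_name = feature_name),
            class = "direction_correlation")
}

#' @export
print.direction_correlation <- function(x, ...) {
  cat(sprintf("<direction_correlation> %s: r = %.4f at theta = %.2f deg (n = %d)\n",
              x$feature_name, x$r, x$theta * 180 / pi, x$n))
  invisible(x)
}

#' Correlation table of an embedding against several features
#'
#' One [best_correlation_direction()] per feature column.
#'
#' @param emb an `oct_embedding`.
#' @param features data.frame of per-image numeric features (rows aligned
#'   with `emb$ids`).
#' @return data.frame with columns `feature`, `theta_deg`, `r`, `abs_r`, `n`.
#' @export
correlation_table <- function(emb, features) {
  out <- do.call(rbind, lapply(names(features), function(nm) {
    dc <- best_correlation_direction(emb, features[[nm]], feature_name = nm)
    data.frame(feature = nm, theta_deg = dc$theta * 180 / pi,
               r = dc$r, abs_r = abs(dc$r), n = dc$n)
  }))
  rownames(out) <- NULL
  out
}

#' Image Map: montage of images over a regular grid in (w, v)
#'
#' Defines a regular `rows x cols` grid spanning the bounding box of the
#' mapped coordinates and displays, at each grid point, the image whose
#' (w, v) is nearest, assigning greedily so that each data point appears in
#' at most one cell (ties broken by id order). Grid points with no data point
#' within half a grid spacing (axis-normalized) stay empty. Axes with zero
#' coordinate extent are expanded symmetrically so a degenerate cluster still
#' renders in a single cell.
#'
#' @param emb an `oct_embedding` (2-D).
#' @param images list of `aligned_image`s (or matrices) aligned with
#'   `emb$ids`; `NULL` skips montage rendering (assignments only).
#' @param grid_shape `c(rows, cols)`, both at least 2.
#' @param cell_px `c(height, width)` of each montage cell in pixels.
#' @return Object of class `image_map_grid`: list with `grid_shape`,
#'   `cell_assignments` (rows x cols matrix of image ids or NA; row 1 = top =
#'   largest v) and `montage` (matrix or NULL).
#' @export
render_image_map <- function(emb, images = NULL, grid_shape = c(6L, 10L),
                             cell_px = c(64L, 96L)) {
  if (any(grid_shape < 2L)) stop("grid_shape must be at least 2 x 2")
  X <- emb$coords
  rng_w <- range(X[, 1]); rng_v <- range(X[, 2])
  if (diff(rng_w) == 0) rng_w <- rng_w + c(-0.5, 0.5)
  if (diff(rng_v) == 0) rng_v <- rng_v + c(-0.5, 0.5)
  rows <- grid_shape[1]; cols <- grid_shape[2]
  gw <- seq(rng_w[1], rng_w[2], length.out = cols)
  gv <- seq(rng_v[2], rng_v[1], length.out = rows)  # top row = largest v
  sw <- diff(rng_w) / (cols - 1); sv <- diff(rng_v) / (rows - 1)
  assign <- matrix(NA_character_, rows, cols)
  taken <- rep(FALSE, nrow(X))
  ord_id <- order(emb$ids)
  for (r in seq_len(rows)) for (c in seq_len(cols)) {
    dd <- sqrt(((X[, 1] - gw[c]) / sw)^2 + ((X[, 2] - gv[r]) / sv)^2)
    dd[taken] <- Inf
    cand <- ord_id[which.min(dd[ord_id])]   # ties resolved by id order
    if (is.finite(dd[cand]) && dd[cand] <= 0.5) {
      assign[r, c] <- emb$ids[cand]
      taken[cand] <- TRUE
    }
  }
  montage <- NULL
  if (!is.null(images)) {
    if (is.null(names(images))) names(images) <- emb$ids
    montage <- matrix(0, rows * cell_px[1], cols * cell_px[2])
    for (r in seq_len(rows)) for (c in seq_len(cols)) {
      id <- assign[r, c]
      if (is.na(id)) next
      thumb <- resize_axis_linear(
        resize_axis_linear(as_pixels(images[[id]]), cell_px[1], "rows"),
        cell_px[2], "cols")
      montage[(r - 1) * cell_px[1] + seq_len(cell_px[1]),
              (c - 1) * cell_px[2] + seq_len(cell_px[2])] <- thumb
    }
  }
  structure(list(grid_shape = grid_shape, cell_assignments = assign,
                 montage = montage),
            class = "image_map_grid")
}

#' @export
print.image_map_grid <- function(x, ...) {
  cat(sprintf("<image_map_grid> %d x %d grid, %d cells occupied\n",
              x$grid_shape[1], x$grid_shape[2],
              sum(!is.na(x$cell_assignments))))
  invisible(x)
}

#' Class-label overlay of an embedding
#'
#' Scatter data of the mapped coordinates colored by class label; images
#' without a label are shown gray. Returns the plotting data (and, when
#' ggplot2 is installed, a ggplot object as attribute `"plot"`).
#'
#' @param emb an `oct_embedding`.
#' @param labels named vector of class labels (names = image ids); may cover
#'   only a subset of images.
#' @return data.frame with columns `id`, `w`, `v`, `label`, `color`.
#' @export
label_overlay <- function(emb, labels = NULL) {
  lab <- rep(NA_character_, length(emb$ids))
  if (!is.null(labels) && length(labels))
    lab <- as.character(labels[emb$ids])
  classes <- sort(unique(lab[!is.na(lab)]))
  pal <- if (length(classes))
    setNames(grDevices::hcl.colors(max(length(classes), 2L), "Dark 2")[seq_along(classes)],
             classes) else character()
  df <- data.frame(id = emb$ids, w = emb$coords[, 1], v = emb$coords[, 2],
                   label = lab,
                   color = ifelse(is.na(lab), "grey60", pal[lab]),
                   stringsAsFactors = FALSE)
  if (requireNamespace("ggplot2", quietly = TRUE)) {
    p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$w, y = .data$v)) +
      ggplot2::geom_point(ggplot2::aes(color = .data$label)) +
      ggplot2::scale_color_manual(values = pal, na.value = "grey60") +
      ggplot2::labs(x = "w", y = "v", color = "class") +
      ggplot2::theme_minimal()
    attr(df, "plot") <- p
  }
  df
}
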