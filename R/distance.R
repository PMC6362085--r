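#' Hellinger distance between two aligned canvases
#'
#' Treats each canvas as a mass distribution and returns
#' `sqrt(2 * sum_ij (sqrt(a_ij / S_a) - sqrt(b_ij / S_b))^2)`, where `S` is
#' the total mass of each canvas. The mass normalization makes the distance
#' invariant under global intensity rescaling of either image; values lie in
#' \[0, 2\], with 2 attained exactly when the supports are disjoint.
#'
#' The normalizing mass is recomputed on the aligned canvas itself (the
#' source mass can differ slightly after resampling), keeping the
#' unit-mass identity `sum a/S = 1` exact.
#'
#' @param a,b `aligned_image` objects (or plain matrices) of identical shape.
#' @return Nonnegative scalar distance.
#' @export
hellinger_distance <- function(a, b) {
  ma <- as_pixels(a); mb <- as_pixels(b)
  if (!identical(dim(ma), dim(mb))) stop("canvas shapes differ")
  Sa <- sum(ma); Sb <- sum(mb)
  if (Sa <= 0 || Sb <= 0) stop("zero-mass image")
  sqrt(2 * sum((sqrt(ma / Sa) - sqrt(mb / Sb))^2))
}

#' Euclidean distance between two aligned canvases
#'
#' `sqrt(sum_ij (a_ij - b_ij)^2)`, with no mass normalization; sensitive to
#' global intensity scale.
#'
#' @inheritParams hellinger_distance
#' @return Nonnegative scalar distance, in intensity units.
#' @export
euclidean_distance <- function(a, b) {
  ma <- as_pixels(a); mb <- as_pixels(b)
  if (!identical(dim(ma), dim(mb))) stop("canvas shapes differ")
  sqrt(sum((ma - mb)^2))
}

#' Pairwise distance matrix over a set of aligned images
#'
#' Computes all `n(n-1)/2` unordered pairwise distances (each pair evaluated
#' once, so the matrix is symmetric by construction with a zero diagonal).
#' Results are independent of evaluation order.
#'
#' @param images list of `aligned_image` objects (or matrices) with identical
#'   shapes.
#' @param metric `"hellinger"` or `"euclidean"`.
#' @param ids image identifiers; defaults to `source_id`s or list names, else
#'   `img_1 ... img_n`.
#' @return Object of class `oct_dist`: the `n x n` numeric matrix with
#'   attributes `metric` and `n_pairs` (number of pair evaluations,
#'   `n(n-1)/2`); row/column names are the ids.
#' @export
pairwise_distances <- function(images, metric = c("hellinger", "euclidean"),
                               ids = NULL) {
  metric <- match.arg(metric)
  n <- length(images)
  if (n < 2L) stop("need at least two images")
  mats <- lapply(images, as_pixels)
  shp <- dim(mats[[1]])
  if (!all(vapply(mats, function(m) identical(dim(m), shp), logical(1))))
    stop("heterogeneous canvas shapes")
  if (is.null(ids)) {
    ids <- vapply(seq_len(n), function(k) {
      im <- images[[k]]
      id <- if (inherits(im, "aligned_image")) im$source_id else NA_character_
      if (is.na(id)) id <- names(images)[k]
      if (is.null(id) || is.na(id) || id == "") id <- paste0("img_", k)
      id
    }, character(1))
  }
  # flatten once; both metrics are Euclidean norms in a transformed space,
  # so stats::dist computes exactly the n(n-1)/2 unordered pairs
  flat <- do.call(rbind, lapply(mats, as.vector))
  if (metric == "hellinger") {
    S <- rowSums(flat)
    if (any(S <= 0)) stop("zero-mass image")
    d <- stats::dist(sqrt(flat / S)) * sqrt(2)
  } else {
    d <- stats::dist(flat)
  }
  D <- as.matrix(d)
  dimnames(D) <- list(ids, ids)
  structure(D, metric = metric, n_pairs = length(d), class = c("oct_dist", "matrix"))
}

#' @export
print.oct_dist <- function(x, ...) {
  cat(sprintf("<oct_dist> %d x %d, metric = %s (%d pairs)\n",
              nrow(x), ncol(x), attr(x, "metric"), attr(x, "n_pairs")))
  invisible(x)
}

#' Write / read a distance matrix as CSV
#'
#' The CSV stores the image ids as the first column and header row.
#'
#' @param D an `oct_dist` (or plain matrix with dimnames).
#' @param path CSV file path.
#' @return `read_distance_csv` returns an `oct_dist`.
#' @export
write_distance_csv <- function(D, path) {
  df <- data.frame(id = rownames(D), as.data.frame(unclass(D)[, , drop = FALSE]),
                   check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_distance_csv
#' @param metric metric label to attach on read.
#' @export
read_distance_csv <- function(path, metric = "hellinger") {
  df <- read.csv(path, check.names = FALSE)
  ids <- as.character(df[[1]])
  D <- as.matrix(df[, -1, drop = FALSE])
  dimnames(D) <- list(ids, ids)
  structure(D, metric = metric, n_pairs = nrow(D) * (nrow(D) - 1) / 2,
            class = c("oct_dist", "matrix"))
}
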