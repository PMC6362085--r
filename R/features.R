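#' Clinical landmark set of one AS-OCT image
#'
#' Landmarks are 2-D points `c(x, y)` in millimetres, in the image frame
#' (x right, y increasing downward, matching image row order). Per side
#' (left/right of the anterior chamber): the scleral spur, a second point
#' near the spur on the inside edge of the cornea (together they set a line
#' approximating the inner corneal edge), and two points on the top edge of
#' the iris (setting the iris line). At the center: points on the inside and
#' outside corneal edge and on the top edge of the lens. Either side may be
#' absent (`NULL`), e.g. when the spur was not visible, but not both.
#'
#' @param left,right `NULL` or list with `scleral_spur` (length-2),
#'   `cornea_inner_aux` (length-2) and `iris_pts` (2 x 2 matrix, one point
#'   per row).
#' @param center list with `cornea_inner`, `cornea_outer`, `lens_top`
#'   (each length-2 or `NULL`).
#' @return Object of class `landmark_set`.
#' @export
landmark_set <- function(left = NULL, right = NULL,
                         center = list(cornea_inner = NULL,
                                       cornea_outer = NULL,
                                       lens_top = NULL)) {
  chk_pt <- function(p, what) {
    if (!is.null(p) && (!is.numeric(p) || length(p) != 2L || any(!is.finite(p))))
      stop(what, " must be a finite length-2 numeric (x, y) in mm")
  }
  chk_side <- function(sd, nm) {
    if (is.null(sd)) return(invisible())
    chk_pt(sd$scleral_spur, paste0(nm, "$scleral_spur"))
    chk_pt(sd$cornea_inner_aux, paste0(nm, "$cornea_inner_aux"))
    if (is.null(sd$iris_pts) || !is.matrix(sd$iris_pts) ||
        !all(dim(sd$iris_pts) == c(2L, 2L)) || any(!is.finite(sd$iris_pts)))
      stop(nm, "$iris_pts must be a 2 x 2 finite matrix")
    if (all(sd$iris_pts[1, ] == sd$iris_pts[2, ]))
      stop(nm, ": the two iris points must be distinct")
    if (all(sd$scleral_spur == sd$cornea_inner_aux))
      stop(nm, ": cornea_inner_aux must differ from scleral_spur")
  }
  chk_side(left, "left"); chk_side(right, "right")
  for (nm in c("cornea_inner", "cornea_outer", "lens_top"))
    chk_pt(center[[nm]], paste0("center$", nm))
  structure(list(left = left, right = right, center = center),
            class = "landmark_set")
}

#' Anterior chamber depth L
#'
#' Euclidean distance (mm) between the central inner corneal edge point and
#' the lens apex.
#'
#' @param lm a [landmark_set()].
#' @return Depth in mm.
#' @export
chamber_depth <- function(lm) {
  a <- lm$center$cornea_inner; b <- lm$center$lens_top
  if (is.null(a) || is.null(b))
    stop("chamber_depth needs center cornea_inner and lens_top landmarks")
  sqrt(sum((a - b)^2))
}

# Unit direction of the line through two points.
line_dir <- function(p, q) {
  d <- q - p
  nd <- sqrt(sum(d^2))
  if (nd == 0) stop("duplicated points define no line")
  d / nd
}

# Intersection of lines p1 + t u1 and p2 + s u2; NULL when parallel.
line_intersect <- function(p1, u1, p2, u2, tol = 1e-12) {
  det <- u1[1] * u2[2] - u1[2] * u2[1]
  if (abs(det) < tol) return(NULL)
  t <- ((p2[1] - p1[1]) * u2[2] - (p2[2] - p1[2]) * u2[1]) / det
  p1 + t * u1
}

#' Iridocorneal angle of one side
#'
#' Approximates the inner corneal edge by the line through the scleral spur
#' and the auxiliary corneal point, and the iris top edge by the line through
#' the two iris points, and returns the acute angle between the two lines at
#' their intersection (the angle recess), in degrees. Parallel lines return 0
#' with a warning.
#'
#' @param lm_side one side (`$left` or `$right`) of a [landmark_set()].
#' @return Angle in degrees, in \[0, 90\].
#' @export
iris_corneal_angle <- function(lm_side) {
  if (is.null(lm_side)) stop("side landmarks are absent")
  u_c <- line_dir(lm_side$scleral_spur, lm_side$cornea_inner_aux)
  u_i <- line_dir(lm_side$iris_pts[1, ], lm_side$iris_pts[2, ])
  if (is.null(line_intersect(lm_side$scleral_spur, u_c,
                             lm_side$iris_pts[1, ], u_i))) {
    warning("cornea and iris lines are parallel; returning angle 0")
    return(0)
  }
  acos(pmin(pmax(abs(sum(u_c * u_i)), -1), 1)) * 180 / pi
}

#' Angle recess area up to 500 um from the scleral spur
#'
#' With both edges approximated as lines: let `A` be their intersection (the
#' recess apex), `P` the point on the cornea line `offset_mm` (0.5 mm by
#' default) from the scleral spur on the side where the two lines open up
#' toward the chamber, and `Q` the foot of the perpendicular from `P` onto
#' the iris line. Returns the area of triangle `(A, P, Q)` in mm^2 — a
#' line-based approximation of the standard angle-recess-area (ARA500)
#' definition, anchored at the scleral spur. The area is homogeneous of
#' degree 2 when the coordinates and `offset_mm` are scaled together.
#'
#' @inheritParams iris_corneal_angle
#' @param offset_mm distance from the scleral spur along the cornea line at
#'   which the recess is closed off (0.5 for the conventional ARA500).
#' @return Area in mm^2.
#' @export
ara500 <- function(lm_side, offset_mm = 0.5) {
  if (is.null(lm_side)) stop("side landmarks are absent")
  spur <- lm_side$scleral_spur
  u_c <- line_dir(spur, lm_side$cornea_inner_aux)
  u_i <- line_dir(lm_side$iris_pts[1, ], lm_side$iris_pts[2, ])
  A <- line_intersect(spur, u_c, lm_side$iris_pts[1, ], u_i)
  if (is.null(A)) stop("cornea and iris lines are parallel: recess apex undefined")
  # candidate offset points on the cornea line; keep the one on the open side
  # of the recess (farther from the iris line)
  perp_dist <- function(p) {
    w <- p - A
    abs(w[1] * u_i[2] - w[2] * u_i[1])
  }
  P1 <- spur + offset_mm * u_c; P2 <- spur - offset_mm * u_c
  P <- if (perp_dist(P1) >= perp_dist(P2)) P1 else P2
  # foot of the perpendicular from P on the iris line
  Q <- A + sum((P - A) * u_i) * u_i
  abs((P[1] - A[1]) * (Q[2] - A[2]) - (Q[1] - A[1]) * (P[2] - A[2])) / 2
}

#' Assemble all annotation features from a landmark set
#'
#' Computes the anterior chamber depth `L`, the per-side iridocorneal angles
#' `alpha` (left) and `beta` (right), their mean, and the per-side ARA500
#' with its minimum. Absent sides yield `NA` for their angle and area (never
#' 0); the mean angle and minimum area are taken over the available sides.
#'
#' @param lm a [landmark_set()]; at least one side must be present.
#' @return Object of class `annotation_features`: list with `L`, `alpha`,
#'   `beta`, `mean_angle`, `ara500_left`, `ara500_right`, `ara500_min`.
#' @export
features_from_landmarks <- function(lm) {
  stopifnot(inherits(lm, "landmark_set"))
  if (is.null(lm$left) && is.null(lm$right))
    stop("both sides absent: no angle features can be computed")
  side_val <- function(sd, f) if (is.null(sd)) NA_real_ else f(sd)
  alpha <- side_val(lm$left, iris_corneal_angle)
  beta <- side_val(lm$right, iris_corneal_angle)
  aL <- side_val(lm$left, ara500)
  aR <- side_val(lm$right, ara500)
  L <- if (is.null(lm$center$cornea_inner) || is.null(lm$center$lens_top))
    NA_real_ else chamber_depth(lm)
  structure(list(
    L = L, alpha = alpha, beta = beta,
    mean_angle = mean(c(alpha, beta), na.rm = TRUE),
    ara500_left = aL, ara500_right = aR,
    ara500_min = suppressWarnings(min(c(aL, aR), na.rm = TRUE))
  ), class = "annotation_features")
}

#' @export
print.annotation_features <- function(x, ...) {
  cat(sprintf(
    "<annotation_features> L = %.3f mm, alpha = %.2f deg, beta = %.2f deg, ARA500 min = %.4f mm^2\n",
    x$L, x$alpha, x$beta, x$ara500_min))
  invisible(x)
}

#' Read / write landmark CSV files
#'
#' One row per landmark: `image_id, landmark_name, side, x_mm, y_mm`.
#' `side` is `left`, `right` or `center`; `landmark_name` is one of
#' `scleral_spur`, `cornea_inner_aux`, `iris_pt1`, `iris_pt2` (sides) and
#' `cornea_inner`, `cornea_outer`, `lens_top` (center).
#'
#' @param path CSV file.
#' @return `read_landmarks_csv` returns a named list of [landmark_set()]s,
#'   one per `image_id`.
#' @export
read_landmarks_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("image_id", "landmark_name", "side", "x_mm", "y_mm")
  if (!all(need %in% names(df)))
    stop("landmark CSV must have columns: ", paste(need, collapse = ", "))
  out <- lapply(split(df, df$image_id), function(d) {
    pick <- function(side, name) {
      r <- d[d$side == side & d$landmark_name == name, , drop = FALSE]
      if (nrow(r) == 0L) NULL else c(r$x_mm[1], r$y_mm[1])
    }
    mk_side <- function(side) {
      sp <- pick(side, "scleral_spur"); ax <- pick(side, "cornea_inner_aux")
      i1 <- pick(side, "iris_pt1"); i2 <- pick(side, "iris_pt2")
      if (is.null(sp) || is.null(ax) || is.null(i1) || is.null(i2)) return(NULL)
      list(scleral_spur = sp, cornea_inner_aux = ax, iris_pts = rbind(i1, i2))
    }
    landmark_set(
      left = mk_side("left"), right = mk_side("right"),
      center = list(cornea_inner = pick("center", "cornea_inner"),
                    cornea_outer = pick("center", "cornea_outer"),
                    lens_top = pick("center", "lens_top"))
    )
  })
  out
}

#' @rdname read_landmarks_csv
#' @param lms named list of [landmark_set()]s (names are image ids).
#' @export
write_landmarks_csv <- function(lms, path) {
  rows <- list()
  add <- function(id, name, side, p) {
    if (!is.null(p))
      rows[[length(rows) + 1L]] <<- data.frame(
        image_id = id, landmark_name = name, side = side,
        x_mm = p[1], y_mm = p[2])
  }
  for (id in names(lms)) {
    lm <- lms[[id]]
    for (side in c("left", "right")) {
      sd <- lm[[side]]
      if (is.null(sd)) next
      add(id, "scleral_spur", side, sd$scleral_spur)
      add(id, "cornea_inner_aux", side, sd$cornea_inner_aux)
      add(id, "iris_pt1", side, sd$iris_pts[1, ])
      add(id, "iris_pt2", side, sd$iris_pts[2, ])
    }
    for (nm in c("cornea_inner", "cornea_outer", "lens_top"))
      add(id, nm, "center", lm$center[[nm]])
  }
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Feature table for a set of landmark files
#'
#' @param lms named list of [landmark_set()]s.
#' @return data.frame, one row per image: `image_id`, `L`, `alpha`, `beta`,
#'   `mean_angle`, `ara500_left`, `ara500_right`, `ara500_min`.
#' @export
features_table <- function(lms) {
  do.call(rbind, lapply(names(lms), function(id) {
    f <- features_from_landmarks(lms[[id]])
    data.frame(image_id = id, L = f$L, alpha = f$alpha, beta = f$beta,
               mean_angle = f$mean_angle, ara500_left = f$ara500_left,
               ara500_right = f$ara500_right, ara500_min = f$ara500_min)
  }))
}
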