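#' Parameters of a synthetic anterior-chamber phantom
#'
#' Describes one synthetic AS-OCT-like cross-section: a bright downward-bowed
#' corneal band (two concentric arcs), two iris bands whose top edges meet the
#' cornea's inner edge at a controllable apex angle on each side, and a lens
#' arc whose apex sits `chamber_depth_mm` below the central inner corneal
#' edge. The whole structure can be rotated in-plane about the image center
#' and translated, and is corrupted by multiplicative lognormal speckle and
#' additive uniform background noise.
#'
#' Defaults mirror a Visante-style anterior-segment scan: 256 x 1024 px
#' covering 8 mm x 16 mm (31.25 um vertical x 15.625 um horizontal spacing).
#'
#' @param width_px,height_px canvas size in pixels.
#' @param px_mm_x,px_mm_y pixel spacing, mm/px.
#' @param iridocorneal_angle_deg apex angle (degrees, per side) between the
#'   cornea inner edge and the iris top edge; must lie in (0, 90).
#' @param chamber_depth_mm distance (mm) from the central cornea inner edge to
#'   the lens apex; must be positive and fit inside the canvas.
#' @param rotation_deg whole-eye in-plane rotation (degrees) about the image
#'   center, applied in physical (mm) coordinates.
#' @param shift_px integer translation `c(di, dj)` (down, right) in pixels.
#' @param speckle_sigma scale of the multiplicative lognormal speckle
#'   `exp(sigma * Z)`, `Z ~ N(0,1)`; 0 disables speckle.
#' @param background_level upper bound of the additive uniform background
#'   noise, in \[0, 1).
#' @param seed integer RNG seed; the same seed and parameters give a
#'   bit-identical image.
#' @return An object of class `phantom_params`.
#' @export
phantom_params <- function(width_px = 1024L, height_px = 256L,
                           px_mm_x = 0.015625, px_mm_y = 0.03125,
                           iridocorneal_angle_deg = 40,
                           chamber_depth_mm = 3,
                           rotation_deg = 0, shift_px = c(0L, 0L),
                           speckle_sigma = 0.5, background_level = 0.05,
                           seed = 1L) {
  if (width_px < 8L || height_px < 8L)
    stop("canvas dimensions must be at least 8 px")
  if (px_mm_x <= 0 || px_mm_y <= 0) stop("pixel spacings must be positive")
  if (iridocorneal_angle_deg <= 0 || iridocorneal_angle_deg >= 90)
    stop("iridocorneal_angle_deg must lie in the open interval (0, 90)")
  if (chamber_depth_mm <= 0) stop("chamber_depth_mm must be positive")
  if (speckle_sigma < 0) stop("speckle_sigma must be nonnegative")
  if (background_level < 0 || background_level >= 1)
    stop("background_level must lie in [0, 1)")
  if (length(shift_px) != 2L) stop("shift_px must have two elements (di, dj)")
  p <- structure(list(
    width_px = as.integer(width_px), height_px = as.integer(height_px),
    px_mm_x = px_mm_x, px_mm_y = px_mm_y,
    iridocorneal_angle_deg = iridocorneal_angle_deg,
    chamber_depth_mm = chamber_depth_mm,
    rotation_deg = rotation_deg, shift_px = as.integer(round(shift_px)),
    speckle_sigma = speckle_sigma, background_level = background_level,
    seed = as.integer(seed)
  ), class = "phantom_params")
  geo <- phantom_geometry(p)
  if (geo$lens$apex[2] + geo$lens$thickness > geo$H)
    stop("chamber_depth_mm too large: lens does not fit inside the canvas")
  p
}

# Analytic scene geometry in physical coordinates (x right, y down, mm),
# before pose. All landmark/feature ground truth derives from these line and
# arc parameters; the rasterizer draws exactly these shapes. Points are (x, y).
phantom_geometry <- function(p) {
  W <- p$width_px * p$px_mm_x
  H <- p$height_px * p$px_mm_y
  s <- W / 16                       # scale factor relative to a 16 mm scan
  xc <- W / 2
  r_out <- 7.8 * s; t_cor <- 0.6 * s
  r_in <- r_out - t_cor
  y_apex <- 0.2 * H                 # outer corneal apex depth
  c_cor <- c(xc, y_apex + r_out)    # shared center of both corneal arcs
  dx_apex <- 5.0 * s                # recess apex lateral offset from center
  half_span <- 5.5 * s              # corneal lateral half extent
  theta <- p$iridocorneal_angle_deg * pi / 180

  side <- function(sgn) {           # sgn = -1 left, +1 right
    ax <- xc + sgn * dx_apex
    ay <- c_cor[2] - sqrt(r_in^2 - dx_apex^2)
    # unit tangent of the inner corneal arc at the apex, pointing toward the
    # image center
    rad <- c(ax - c_cor[1], ay - c_cor[2]) / r_in
    tang <- c(-rad[2], rad[1])
    if (tang[1] * sgn > 0) tang <- -tang            # x-component toward center
    # iris top edge: the tangent rotated by theta into the chamber (toward +y)
    rot <- function(v, a) c(cos(a) * v[1] - sin(a) * v[2],
                            sin(a) * v[1] + cos(a) * v[2])
    iris_dir <- rot(tang, if (sgn < 0) theta else -theta)
    list(apex = c(ax, ay), tangent = tang, iris_dir = iris_dir)
  }

  list(
    W = W, H = H, xc = xc, scale = s,
    cornea = list(center = c_cor, r_out = r_out, r_in = r_in,
                  half_span = half_span, y_apex = y_apex),
    inner_apex = c(xc, y_apex + t_cor),
    left = side(-1), right = side(+1),
    iris_thickness = 0.45 * s,
    pupil_half = 1.5 * s,
    lens = list(apex = c(xc, y_apex + t_cor + p$chamber_depth_mm),
                r = 10 * s, thickness = 0.35 * s, half_span = 2.4 * s),
    intensities = c(cornea = 0.9, iris = 0.7, lens = 0.5)
  )
}

# Rasterize the noiseless, unposed scene. Returns the intensity matrix.
phantom_raster <- function(p, geo = phantom_geometry(p)) {
  nr <- p$height_px; nc <- p$width_px
  X <- matrix(rep((seq_len(nc) - 0.5) * p$px_mm_x, each = nr), nr, nc)
  Y <- matrix(rep((seq_len(nr) - 0.5) * p$px_mm_y, times = nc), nr, nc)
  img <- matrix(0, nr, nc)
  co <- geo$cornea
  d_cor <- sqrt((X - co$center[1])^2 + (Y - co$center[2])^2)
  cornea <- d_cor >= co$r_in & d_cor <= co$r_out &
    Y <= co$center[2] & abs(X - geo$xc) <= co$half_span
  chamber <- d_cor < co$r_in        # region below the inner corneal edge
  iris_band <- function(sd) {
    dir <- sd$iris_dir
    nrm <- c(-dir[2], dir[1])                   # rotate +90 deg: chamber side
    if (nrm[2] < 0) nrm <- -nrm
    u <- (X - sd$apex[1]) * dir[1] + (Y - sd$apex[2]) * dir[2]
    w <- (X - sd$apex[1]) * nrm[1] + (Y - sd$apex[2]) * nrm[2]
    x_pupil <- geo$xc + sign(geo$xc - sd$apex[1]) * -geo$pupil_half
    u_max <- (x_pupil - sd$apex[1]) / dir[1]
    u >= 0 & u <= u_max & w >= 0 & w <= geo$iris_thickness & chamber
  }
  le <- geo$lens
  c_lens <- c(le$apex[1], le$apex[2] + le$r)
  d_lens <- sqrt((X - c_lens[1])^2 + (Y - c_lens[2])^2)
  lens <- d_lens <= le$r & d_lens >= le$r - le$thickness &
    Y <= c_lens[2] & abs(X - geo$xc) <= le$half_span
  ints <- geo$intensities
  img <- pmax(ints["cornea"] * cornea,
              pmax(ints["iris"] * (iris_band(geo$left) | iris_band(geo$right)),
                   ints["lens"] * lens))
  unname(img)
}

# Pose warp shared by image and mask: rotation by rotation_deg about the
# physical image center (mm frame, so anisotropic pixels still see a rigid
# rotation), then integer translation; one bilinear backward gather.
phantom_pose_warp <- function(m, p) {
  warp_pose_matrix(m, p$px_mm_x, p$px_mm_y, p$rotation_deg, p$shift_px)
}

#' Generate one synthetic phantom image
#'
#' Rasterizes the analytic scene of [phantom_params()], applies the in-plane
#' pose (rotation then translation, one bilinear resampling, zero fill), then
#' multiplies by lognormal speckle and adds uniform background noise, clipping
#' to \[0, 1\]. Fully deterministic given the parameters.
#'
#' @param params a [phantom_params()] object.
#' @return A [gray_image]; the generating `params` are attached as attribute
#'   `"params"`.
#' @seealso [phantom_mask()], [phantom_true_angle()], [phantom_landmarks()]
#' @export
generate_phantom <- function(params) {
  stopifnot(inherits(params, "phantom_params"))
  img <- phantom_pose_warp(phantom_raster(params), params)
  if (params$speckle_sigma > 0 || params$background_level > 0) {
    img <- with_seed(params$seed, {
      out <- img
      if (params$speckle_sigma > 0)
        out <- out * exp(params$speckle_sigma *
                           matrix(rnorm(length(out)), nrow(out)))
      if (params$background_level > 0)
        out <- out + matrix(runif(length(out), 0, params$background_level),
                            nrow(out))
      out
    })
  }
  img <- pmin(pmax(img, 0), 1)
  g <- gray_image(img, params$px_mm_x, params$px_mm_y)
  attr(g, "params") <- params
  g
}

#' Anatomical support mask of a phantom
#'
#' Binary mask (posed like the image) of the pixels touched by the corneal,
#' iris, or lens bands. In a noiseless phantom (`speckle_sigma = 0`,
#' `background_level = 0`) every nonzero pixel lies inside this mask.
#'
#' @inheritParams generate_phantom
#' @return Logical matrix of the same size as the image.
#' @export
phantom_mask <- function(params) {
  m <- phantom_raster(params) > 0
  phantom_pose_warp(m * 1, params) > 1e-12
}

#' Ground-truth apex angle re-measured from the analytic edge lines
#'
#' Recomputes, per side, the angle between the iris top-edge line and the
#' tangent of the inner corneal arc at the recess apex, directly from the
#' generator's internal line parameters (independent of the raster).
#'
#' @inheritParams generate_phantom
#' @return Named numeric `c(left = , right = )`, degrees.
#' @export
phantom_true_angle <- function(params) {
  geo <- phantom_geometry(params)
  ang <- function(sd) {
    d <- abs(sum(sd$tangent * sd$iris_dir)) /
      (sqrt(sum(sd$tangent^2)) * sqrt(sum(sd$iris_dir^2)))
    acos(pmin(pmax(d, -1), 1)) * 180 / pi
  }
  c(left = ang(geo$left), right = ang(geo$right))
}

# Forward pose transform of (x, y) mm points, matching phantom_pose_warp.
phantom_pose_points <- function(pts, p) {
  W <- p$width_px * p$px_mm_x; H <- p$height_px * p$px_mm_y
  ctr <- c(W / 2, H / 2)
  a <- p$rotation_deg * pi / 180
  shift_mm <- c(p$shift_px[2] * p$px_mm_x, p$shift_px[1] * p$px_mm_y)
  t(apply(pts, 1L, function(q) {
    d <- q - ctr
    # rot2 acts on (i, j) = (y, x); written out here for (x, y)
    c(ctr[1] + sin(a) * d[2] + cos(a) * d[1],
      ctr[2] + cos(a) * d[2] - sin(a) * d[1]) + shift_mm
  }))
}

#' Ground-truth landmark set of a phantom
#'
#' Emits the clinical landmark set an annotator would place, derived exactly
#' from the analytic scene: scleral spur at each recess apex, an auxiliary
#' point on the inner-cornea tangent line, two points on each iris top edge,
#' the central inner/outer corneal edge points and the lens apex. Landmarks
#' are posed with the same rotation/translation as the image.
#'
#' @inheritParams generate_phantom
#' @return A [landmark_set()].
#' @export
phantom_landmarks <- function(params) {
  geo <- phantom_geometry(params)
  pose <- function(m) phantom_pose_points(m, params)
  mk_side <- function(sd) {
    aux <- sd$apex + 0.4 * sd$tangent
    iris <- rbind(sd$apex + 0.5 * sd$iris_dir, sd$apex + 1.5 * sd$iris_dir)
    pts <- pose(rbind(sd$apex, aux, iris))
    list(scleral_spur = pts[1, ], cornea_inner_aux = pts[2, ],
         iris_pts = pts[3:4, , drop = FALSE])
  }
  ctr_pts <- pose(rbind(geo$inner_apex,
                        c(geo$xc, geo$cornea$y_apex),
                        geo$lens$apex))
  landmark_set(
    left = mk_side(geo$left), right = mk_side(geo$right),
    center = list(cornea_inner = ctr_pts[1, ], cornea_outer = ctr_pts[2, ],
                  lens_top = ctr_pts[3, ])
  )
}

#' Generate a cohort of phantoms with sampled geometry and pose
#'
#' Samples the iridocorneal angle and chamber depth uniformly in the given
#' ranges and the pose from `pose_jitter`, derives one child seed per phantom
#' deterministically from `seed`, and returns images together with their
#' ground-truth parameters.
#'
#' @param n number of phantoms (>= 1).
#' @param angle_range,depth_range length-2 numeric ranges (degrees, mm).
#' @param pose_jitter list with `rot_deg` (rotation sampled uniformly in
#'   +/- rot_deg) and `shift_px` (each shift component uniform integer in
#'   +/- shift_px).
#' @param seed cohort seed.
#' @param base_params template [phantom_params()] supplying canvas size,
#'   spacing and noise levels.
#' @return List of `n` elements, each `list(image = gray_image,
#'   params = phantom_params)`.
#' @export
generate_cohort <- function(n, angle_range = c(10, 70),
                            depth_range = c(2.5, 3.5),
                            pose_jitter = list(rot_deg = 10, shift_px = 8),
                            seed = 1L, base_params = phantom_params()) {
  if (n < 1) stop("n must be at least 1")
  if (diff(range(angle_range)) <= 0 || diff(range(depth_range)) <= 0)
    stop("angle_range and depth_range must be nondegenerate")
  draws <- with_seed(seed, list(
    angle = runif(n, angle_range[1], angle_range[2]),
    depth = runif(n, depth_range[1], depth_range[2]),
    rot   = runif(n, -pose_jitter$rot_deg, pose_jitter$rot_deg),
    di    = sample(seq(-pose_jitter$shift_px, pose_jitter$shift_px), n, TRUE),
    dj    = sample(seq(-pose_jitter$shift_px, pose_jitter$shift_px), n, TRUE),
    child = sample.int(.Machine$integer.max - 1L, n)
  ))
  lapply(seq_len(n), function(k) {
    p <- phantom_params(
      width_px = base_params$width_px, height_px = base_params$height_px,
      px_mm_x = base_params$px_mm_x, px_mm_y = base_params$px_mm_y,
      iridocorneal_angle_deg = draws$angle[k],
      chamber_depth_mm = draws$depth[k],
      rotation_deg = draws$rot[k], shift_px = c(draws$di[k], draws$dj[k]),
      speckle_sigma = base_params$speckle_sigma,
      background_level = base_params$background_level,
      seed = draws$child[k]
    )
    list(image = generate_phantom(p), params = p)
  })
}

# Evaluate `expr` under a fixed seed without disturbing the caller's RNG.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
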