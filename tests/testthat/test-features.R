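mk_side <- function(spur, aux, i1, i2)
  list(scleral_spur = spur, cornea_inner_aux = aux, iris_pts = rbind(i1, i2))

# recess at the origin: cornea line along u_c, iris line along u_i
angle_side <- function(theta_deg, spur = c(0, 0)) {
  th <- theta_deg * pi / 180
  mk_side(spur, spur + c(1, 0), c(0, 0), c(cos(th), sin(th)))
}

test_that("chamber depth is the Euclidean landmark distance", {
  lm <- landmark_set(left = angle_side(45),
                     center = list(cornea_inner = c(0, 0), cornea_outer = c(0, -0.6),
                                   lens_top = c(0, 3)))
  expect_equal(chamber_depth(lm), 3)
  lm$center$lens_top <- c(0, 0)
  expect_equal(chamber_depth(lm), 0)
  set.seed(41)
  a <- runif(2, -5, 5); b <- runif(2, -5, 5)
  lm$center$cornea_inner <- a; lm$center$lens_top <- b
  expect_equal(chamber_depth(lm), sqrt(sum((a - b)^2)))
})

test_that("iridocorneal angle equals the acute line-line angle", {
  expect_equal(iris_corneal_angle(angle_side(45)), 45)
  expect_equal(iris_corneal_angle(angle_side(30)), 30, tolerance = 1e-9)
  # identical directions: parallel -> 0 with warning
  par <- mk_side(c(0, 0), c(1, 0), c(0, 1), c(1, 1))
  expect_warning(a0 <- iris_corneal_angle(par), "parallel")
  expect_equal(a0, 0)
  # random pair vs arccos oracle
  set.seed(42)
  for (k in 1:10) {
    u <- runif(2, -1, 1); v <- runif(2, -1, 1)
    sd <- mk_side(c(0, 0), u, c(0, 0), v)
    ref <- acos(abs(sum(u * v)) / sqrt(sum(u^2) * sum(v^2))) * 180 / pi
    expect_equal(iris_corneal_angle(sd), ref, tolerance = 1e-9)
  }
})

test_that("ARA500 matches the constructed-triangle shoelace oracle", {
  for (th in c(30, 45, 60)) {
    # spur at the apex: P is 0.5 mm along the cornea line, |AQ| = 0.5 cos(th),
    # |PQ| = 0.5 sin(th) -> area = 0.125 sin(th) cos(th)
    a <- ara500(angle_side(th))
    thr <- th * pi / 180
    expect_equal(a, 0.125 * sin(thr) * cos(thr), tolerance = 1e-12)
  }
  # degenerate limit: area vanishes with the angle
  th <- 0.001 * pi / 180
  expect_equal(ara500(angle_side(0.001)), 0.125 * sin(th) * cos(th),
               tolerance = 1e-9)
  expect_lt(ara500(angle_side(0.001)), 1e-5)
  # quadratic homogeneity when coordinates and anchor offset scale together
  sd1 <- angle_side(37, spur = c(0.3, 0.2))
  sd2 <- lapply(sd1, function(p) p * 2)
  expect_equal(ara500(sd2, offset_mm = 1), 4 * ara500(sd1), tolerance = 1e-12)
})

test_that("feature assembly handles symmetry and missing sides", {
  lm <- landmark_set(left = angle_side(40), right = angle_side(40, c(4, 0)),
                     center = list(cornea_inner = c(2, 0), cornea_outer = c(2, -0.5),
                                   lens_top = c(2, 3)))
  f <- features_from_landmarks(lm)
  expect_equal(f$alpha, f$beta)
  expect_equal(f$mean_angle, f$alpha)
  expect_equal(f$ara500_min, f$ara500_left)

  one <- landmark_set(left = angle_side(25),
                      center = list(cornea_inner = c(0, 0), cornea_outer = NULL,
                                    lens_top = c(0, 2.5)))
  f1 <- features_from_landmarks(one)
  expect_true(is.na(f1$beta) && is.na(f1$ara500_right))
  expect_equal(f1$ara500_min, f1$ara500_left)
  expect_equal(f1$mean_angle, f1$alpha)

  expect_error(features_from_landmarks(landmark_set(
    center = list(cornea_inner = c(0, 0), cornea_outer = NULL, lens_top = c(0, 1)))),
    "both sides")
})

test_that("features are invariant under rigid motions and scale correctly", {
  lm <- landmark_set(left = angle_side(33, c(-3, 1)),
                     right = angle_side(51, c(3.5, 1.2)),
                     center = list(cornea_inner = c(0, 0.8),
                                   cornea_outer = c(0, 0.2),
                                   lens_top = c(0.1, 3.9)))
  f0 <- features_from_landmarks(lm)
  rigid <- function(p, th, t) {
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
    as.numeric(R %*% p) + t
  }
  move_lm <- function(lm, fun) {
    mv_side <- function(sd) if (is.null(sd)) NULL else
      list(scleral_spur = fun(sd$scleral_spur),
           cornea_inner_aux = fun(sd$cornea_inner_aux),
           iris_pts = t(apply(sd$iris_pts, 1, fun)))
    landmark_set(left = mv_side(lm$left), right = mv_side(lm$right),
                 center = lapply(lm$center, function(p)
                   if (is.null(p)) NULL else fun(p)))
  }
  fr <- features_from_landmarks(
    move_lm(lm, function(p) rigid(p, 0.7, c(2.3, -1.1))))
  expect_equal(fr$L, f0$L, tolerance = 1e-12)
  expect_equal(fr$alpha, f0$alpha, tolerance = 1e-9)
  expect_equal(fr$beta, f0$beta, tolerance = 1e-9)
  expect_equal(fr$ara500_min, f0$ara500_min, tolerance = 1e-9)

  lm3 <- move_lm(lm, function(p) 3 * p)
  fs <- features_from_landmarks(lm3)
  expect_equal(fs$L, 3 * f0$L, tolerance = 1e-12)
  expect_equal(fs$alpha, f0$alpha, tolerance = 1e-9)
  expect_equal(ara500(lm3$left, offset_mm = 1.5), 9 * f0$ara500_left,
               tolerance = 1e-9)
})

test_that("landmark CSVs round-trip through read/write", {
  lms <- list(img_a = phantom_landmarks(test_phantom_params()),
              img_b = phantom_landmarks(test_phantom_params(
                iridocorneal_angle_deg = 22, rotation_deg = 8)))
  f <- tempfile(fileext = ".csv")
  write_landmarks_csv(lms, f)
  back <- read_landmarks_csv(f)
  t0 <- features_table(lms)
  t1 <- features_table(back)
  expect_equal(t1[order(t1$image_id), ], t0[order(t0$image_id), ],
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("landmark validation rejects malformed sets", {
  expect_error(landmark_set(left = mk_side(c(0, 0), c(0, 0), c(0, 1), c(1, 1))),
               "differ")
  expect_error(landmark_set(left = mk_side(c(0, 0), c(1, 0), c(1, 1), c(1, 1))),
               "distinct")
  expect_error(landmark_set(center = list(cornea_inner = c(1, NA),
                                          cornea_outer = NULL, lens_top = NULL)),
               "finite")
})
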