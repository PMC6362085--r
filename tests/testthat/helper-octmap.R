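# Shared fixtures. Test-scale phantoms keep the instrument's 16 mm x 8 mm
# field of view and 2:1 spacing anisotropy but sample it at a quarter of the
# native resolution, which keeps whole-cohort runs fast.

test_phantom_params <- function(...) {
  phantom_params(width_px = 256L, height_px = 64L,
                 px_mm_x = 16 / 256, px_mm_y = 8 / 64, ...)
}

# memoised heavy fixtures, shared across test files within one run
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, .fixture_cache)) assign(key, expr, .fixture_cache)
  get(key, .fixture_cache)
}

# cohort of preprocessed test-scale phantoms with ground truth
preprocessed_cohort <- function(n, seed) {
  cached(sprintf("cohort_%d_%d", n, seed), {
    coh <- generate_cohort(n, seed = seed, base_params = test_phantom_params())
    list(
      aligned = lapply(seq_along(coh), function(k)
        preprocess_image(coh[[k]]$image, source_id = sprintf("ph%03d", k))),
      angle = vapply(coh, function(x) x$params$iridocorneal_angle_deg, numeric(1)),
      depth = vapply(coh, function(x) x$params$chamber_depth_mm, numeric(1))
    )
  })
}

# brute-force raw moments on 0-based indices (integer-exact on integer input)
moments_oracle <- function(m) {
  S <- X <- Y <- XX <- YY <- XY <- 0
  for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m))) {
    v <- m[i, j]; ii <- i - 1; jj <- j - 1
    S <- S + v; X <- X + jj * v; Y <- Y + ii * v
    XX <- XX + jj^2 * v; YY <- YY + ii^2 * v; XY <- XY + ii * jj * v
  }
  list(S = S, X = X, Y = Y, XX = XX, YY = YY, XY = XY)
}

# direct-loop Perona-Malik update (replicated edges), independent of the
# vectorized implementation
pm_oracle <- function(m, n_iter, kappa, lam) {
  nr <- nrow(m); nc <- ncol(m)
  g <- function(d) exp(-(d / kappa)^2)
  for (it in seq_len(n_iter)) {
    out <- m
    for (i in seq_len(nr)) for (j in seq_len(nc)) {
      dN <- m[max(i - 1, 1), j] - m[i, j]
      dS <- m[min(i + 1, nr), j] - m[i, j]
      dW <- m[i, max(j - 1, 1)] - m[i, j]
      dE <- m[i, min(j + 1, nc)] - m[i, j]
      out[i, j] <- m[i, j] +
        lam * (g(dN) * dN + g(dS) * dS + g(dE) * dE + g(dW) * dW)
    }
    m <- out
  }
  m
}

# scalar double-loop Hellinger / Euclidean oracles
hellinger_oracle <- function(a, b) {
  Sa <- sum(a); Sb <- sum(b)
  acc <- 0
  for (i in seq_len(nrow(a))) for (j in seq_len(ncol(a)))
    acc <- acc + (sqrt(a[i, j] / Sa) - sqrt(b[i, j] / Sb))^2
  sqrt(2 * acc)
}

euclidean_oracle <- function(a, b) {
  acc <- 0
  for (i in seq_len(nrow(a))) for (j in seq_len(ncol(a)))
    acc <- acc + (a[i, j] - b[i, j])^2
  sqrt(acc)
}
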