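line_dist <- function(x) {
  D <- abs(outer(x, x, "-"))
  dimnames(D) <- NULL
  D
}

test_that("IsoMap recovers a 1-D line from its distance matrix", {
  set.seed(31)
  x <- sort(runif(20, 0, 10))
  emb <- isomap_embed(line_dist(x), k = 3)
  expect_gte(abs(cor(emb$coords[, 1], x)), 0.999)
})

test_that("IsoMap embeds an equilateral triangle symmetrically", {
  D <- matrix(1, 3, 3); diag(D) <- 0
  emb <- isomap_embed(D, k = 2)
  d <- dist(emb$coords)
  expect_lt(max(d) - min(d), 1e-6)
})

test_that("disconnected neighborhood graphs raise an informative error", {
  x <- c(0, 0.1, 0.2, 0.3, 10, 10.1, 10.2, 10.3)
  expect_error(isomap_embed(line_dist(x), k = 2), "disconnected")
  expect_error(isomap_embed(line_dist(x), k = 2), "component")
  # raising k reconnects
  expect_silent(isomap_embed(line_dist(x), k = 4))
})

test_that("t-SNE is reproducible and centered for a fixed seed", {
  coh <- preprocessed_cohort(20, seed = 32)
  D <- pairwise_distances(coh$aligned, "hellinger")
  e1 <- tsne_embed(D, perplexity = 5, seed = 3)
  e2 <- tsne_embed(D, perplexity = 5, seed = 3)
  expect_identical(e1$coords, e2$coords)
  expect_lt(max(abs(colMeans(e1$coords))), 1e-8)
  er <- tsne_embed(D, perplexity = 5, seed = 3, init = "random", n_restarts = 2)
  expect_identical(er$coords,
                   tsne_embed(D, perplexity = 5, seed = 3, init = "random",
                              n_restarts = 2)$coords)
})

test_that("t-SNE separates two well-separated phantom clusters", {
  narrow <- generate_cohort(10, angle_range = c(12, 16), seed = 33,
                            base_params = test_phantom_params())
  open <- generate_cohort(10, angle_range = c(60, 64), seed = 34,
                          base_params = test_phantom_params())
  al <- lapply(c(narrow, open), function(x) preprocess_image(x$image))
  D <- pairwise_distances(al, "hellinger")
  emb <- tsne_embed(D, perplexity = 5, seed = 0)
  km <- kmeans(emb$coords, centers = 2, nstart = 10)
  truth <- rep(1:2, each = 10)
  agree <- max(mean(km$cluster == truth), mean(km$cluster == 3 - truth))
  expect_equal(agree, 1)
})

test_that("duplicate points land among the very closest embedded pairs", {
  set.seed(35)
  n <- 60
  pts <- matrix(rnorm(2 * n), ncol = 2)
  pts[n, ] <- pts[n - 1, ]        # exact duplicate -> zero distance
  D <- as.matrix(dist(pts)); dimnames(D) <- NULL
  emb <- tsne_embed(D, perplexity = 10, seed = 1)
  de <- as.matrix(dist(emb$coords))
  dup <- de[n - 1, n]
  q <- quantile(de[upper.tri(de)], 0.01)
  expect_lte(dup, q)
})

test_that("perplexity bounds are enforced", {
  D <- line_dist(1:10)
  expect_error(tsne_embed(D, perplexity = 1), "perplexity")
  expect_error(tsne_embed(D, perplexity = 3), "perplexity")
})

test_that("residual variance matches its correlation formula and orderings", {
  set.seed(36)
  x <- sort(runif(20))
  emb <- isomap_embed(line_dist(x), k = 3)
  expect_lte(residual_variance(line_dist(x), emb), 1e-6)

  # formula oracle: 1 - cor^2 over flattened upper triangles, direct loop
  coh <- preprocessed_cohort(20, seed = 32)
  D <- pairwise_distances(coh$aligned, "hellinger")
  e <- tsne_embed(D, perplexity = 5, seed = 0)
  de <- as.matrix(dist(e$coords))
  v1 <- c(); v2 <- c()
  for (l in 1:19) for (m in (l + 1):20) {
    v1 <- c(v1, D[l, m]); v2 <- c(v2, de[l, m])
  }
  expect_equal(residual_variance(D, e), 1 - cor(v1, v2)^2, tolerance = 1e-12)

  # fitted embedding beats a random one on structured distances (n = 100)
  set.seed(37)
  pts <- cbind(runif(100), runif(100))
  Ds <- as.matrix(dist(pts)); dimnames(Ds) <- NULL
  fit <- isomap_embed(Ds, k = 10)
  rnd <- fit
  rnd$coords <- matrix(rnorm(200), 100, 2)
  rnd$geodesic <- fit$geodesic
  expect_lt(residual_variance(Ds, fit), residual_variance(Ds, rnd))
})

test_that("IsoMap residual variance weakly decreases with dimension", {
  set.seed(38)
  # a noisy 2-D sheet: needs two coordinates, so dims = 2 must fit better
  pts <- cbind(runif(60, 0, 4), runif(60, 0, 2))
  D <- as.matrix(dist(pts)); dimnames(D) <- NULL
  e1 <- isomap_embed(D, k = 8, dims = 1)
  e2 <- isomap_embed(D, k = 8, dims = 2)
  expect_lte(residual_variance(D, e2), residual_variance(D, e1))
})

test_that("IsoMap embedding is invariant (up to rigid motion) to id order", {
  skip_if_not_installed("vegan")
  set.seed(39)
  pts <- cbind(runif(30), runif(30))
  D <- as.matrix(dist(pts)); dimnames(D) <- NULL
  e <- isomap_embed(D, k = 6)
  perm <- sample(30)
  ep <- isomap_embed(D[perm, perm], k = 6)
  back <- ep$coords[order(perm), ]
  pr <- vegan::procrustes(e$coords, back, symmetric = TRUE)
  expect_lt(pr$ss, 1e-6)
})
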