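new_embedding <- function(coords, method, params, ids, extra = list()) {
  colnames(coords) <- c("w", "v")[seq_len(ncol(coords))]
  obj <- c(list(coords = coords, method = method, params = params, ids = ids),
           extra)
  class(obj) <- "oct_embedding"
  obj
}

#' @export
print.oct_embedding <- function(x, ...) {
  cat(sprintf("<oct_embedding> %s, %d points x %d dims\n",
              x$method, nrow(x$coords), ncol(x$coords)))
  invisible(x)
}

validate_dist_input <- function(D) {
  D <- unclass(as.matrix(D))
  if (nrow(D) != ncol(D)) stop("distance matrix must be square")
  if (any(!is.finite(D)) || any(D < 0)) stop("distances must be finite and nonnegative")
  if (max(abs(D - t(D))) > 1e-8) stop("distance matrix must be symmetric")
  D
}

#' IsoMap embedding of a precomputed distance matrix
#'
#' Classical IsoMap run directly on a precomputed distance matrix: build the
#' symmetrized k-nearest-neighbor graph, replace distances by shortest-path
#' geodesics along that graph, and apply classical multidimensional scaling,
#' keeping the leading `dims` coordinates (the mapped coordinates (w, v) for
#' `dims = 2`). No re-featurization of the images takes place. The output is
#' deterministic.
#'
#' @param D `oct_dist` or symmetric numeric matrix.
#' @param k neighborhood size of the k-NN graph.
#' @param dims embedding dimension.
#' @return An `oct_embedding` with the geodesic matrix attached (used by
#'   [residual_variance()]).
#' @export
isomap_embed <- function(D, k = 12L, dims = 2L) {
  ids <- rownames(as.matrix(D))
  D <- validate_dist_input(D)
  n <- nrow(D)
  if (k < 1L) stop("k must be at least 1")
  if (n < 3L) stop("need at least 3 points")
  if (is.null(ids)) ids <- paste0("img_", seq_len(n))
  # symmetrized k-NN adjacency
  A <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    nb <- order(D[i, ])[-1][seq_len(min(k, n - 1L))]
    A[i, nb] <- TRUE
  }
  A <- A | t(A)
  g <- igraph::graph_from_adjacency_matrix(A * D, mode = "undirected",
                                           weighted = TRUE)
  comp <- igraph::components(g)
  if (comp$no > 1L)
    stop(sprintf(
      "k-NN graph is disconnected (%d components of sizes %s); increase k",
      comp$no, paste(comp$csize, collapse = ", ")))
  G <- igraph::distances(g, algorithm = "dijkstra")
  mds <- cmdscale(G, k = dims)
  if (ncol(mds) < dims)
    mds <- cbind(mds, matrix(0, n, dims - ncol(mds)))
  dimnames(G) <- NULL
  new_embedding(mds, "isomap", list(k = k, dims = dims), ids,
                extra = list(geodesic = G))
}

#' t-SNE embedding of a precomputed distance matrix
#'
#' Exact (non-approximated) t-distributed stochastic neighbor embedding run
#' in precomputed-distance mode: input-space affinities are Gaussian in the
#' squared given distances, with per-point bandwidths calibrated by binary
#' search to the target perplexity; the low-dimensional map uses the Student-t
#' kernel and is optimized by gradient descent with momentum, adaptive gains
#' and early exaggeration. The run is fully reproducible for a fixed seed,
#' and the returned coordinates are centered at the origin.
#'
#' The default initial configuration is classical MDS of `D` rescaled to a
#' small norm: it is deterministic and anchors the global arrangement, making
#' the final map far less sensitive to the optimization's local minima than a
#' random start (`init = "random"`, which draws from the seed).
#'
#' t-SNE's objective is non-convex and a single run can land in a folded
#' local minimum. With `n_restarts > 1` the optimization is repeated (first
#' from the MDS initialization, then from seeded random starts) and the
#' solution with the lowest Kullback-Leibler divergence — t-SNE's own loss —
#' is kept, which is the standard remedy; the selection is deterministic
#' given `seed`.
#'
#' @param D `oct_dist` or symmetric numeric matrix.
#' @param perplexity target perplexity; must satisfy
#'   `1 < perplexity < (n - 1) / 3`.
#' @param seed RNG seed for the initial configuration (used by
#'   `init = "random"`).
#' @param n_iter gradient-descent iterations.
#' @param eta learning rate; `NULL` (default) uses the standard automatic
#'   rate `max(n / (4 * exaggeration), 50)`, which avoids the divergence
#'   high fixed rates cause on small inputs.
#' @param init `"mds"` (default) or `"random"`.
#' @param exaggeration,exag_iter early-exaggeration factor and the number of
#'   initial iterations it is applied for.
#' @param n_restarts number of optimization runs; the lowest-KL map is kept.
#' @return An `oct_embedding` (2-D); `params$kl` records the final
#'   Kullback-Leibler divergence of the kept run.
#' @export
tsne_embed <- function(D, perplexity = 30, seed = 0L, n_iter = 1000L,
                       eta = NULL, init = c("mds", "random"),
                       exaggeration = 12, exag_iter = 250L,
                       n_restarts = 1L) {
  init <- match.arg(init)
  ids <- rownames(as.matrix(D))
  D <- validate_dist_input(D)
  n <- nrow(D)
  if (is.null(ids)) ids <- paste0("img_", seq_len(n))
  if (perplexity <= 1 || perplexity >= (n - 1) / 3)
    stop("perplexity must satisfy 1 < perplexity < (n - 1)/3")
  if (n_restarts < 1L) stop("n_restarts must be at least 1")
  if (is.null(eta)) eta <- max(n / (4 * exaggeration), 50)
  P <- cond_gaussian_p(D^2, perplexity)
  P <- (P + t(P)) / (2 * n)
  P <- pmax(P, 1e-12)
  mds_init <- function() {
    Y0 <- cmdscale(D, k = 2)
    if (ncol(Y0) < 2) Y0 <- cbind(Y0, 0)
    Y0 / max(sd(Y0[, 1]), .Machine$double.eps) * 1e-4
  }
  inits <- lapply(seq_len(n_restarts), function(k) {
    if (k == 1L && init == "mds") mds_init()
    else with_seed(seed + k - 1L, matrix(rnorm(n * 2, sd = 1e-4), n, 2))
  })
  best <- NULL
  for (Y in inits) {
    G <- matrix(0, n, 2); gains <- matrix(1, n, 2)
    exag_until <- min(exag_iter, n_iter)
    for (it in seq_len(n_iter)) {
      Pe <- if (it <= exag_until) P * exaggeration else P
      sq <- rowSums(Y^2)
      num <- 1 / (1 + outer(sq, sq, "+") - 2 * tcrossprod(Y))
      diag(num) <- 0
      Q <- pmax(num / sum(num), 1e-12)
      W <- (Pe - Q) * num
      grad <- 4 * (diag(rowSums(W)) - W) %*% Y
      mom <- if (it <= exag_until) 0.5 else 0.8
      gains <- ifelse(sign(grad) != sign(G), gains + 0.2, gains * 0.8)
      gains[gains < 0.01] <- 0.01
      G <- mom * G - eta * gains * grad
      Y <- Y + G
      Y <- sweep(Y, 2, colMeans(Y))
    }
    sq <- rowSums(Y^2)
    num <- 1 / (1 + outer(sq, sq, "+") - 2 * tcrossprod(Y))
    diag(num) <- 0
    Q <- pmax(num / sum(num), 1e-12)
    kl <- sum(P * log(P / Q))
    if (is.null(best) || kl < best$kl) best <- list(Y = Y, kl = kl)
  }
  new_embedding(best$Y, "tsne",
                list(perplexity = perplexity, seed = seed, n_iter = n_iter,
                     eta = eta, init = init, exaggeration = exaggeration,
                     exag_iter = exag_iter, n_restarts = n_restarts,
                     kl = best$kl), ids)
}

# Row-conditional Gaussian affinities p_{j|i} at a fixed perplexity, by
# binary search on each row's precision beta (squared distances in D2).
cond_gaussian_p <- function(D2, perplexity) {
  n <- nrow(D2)
  target <- log(perplexity)
  P <- matrix(0, n, n)
  for (i in seq_len(n)) {
    di <- D2[i, -i]
    lo <- 0; hi <- Inf; beta <- 1
    for (iter in 1:64) {
      p <- exp(-di * beta)
      sp <- sum(p)
      if (sp <= 0) { H <- 0; p[] <- 0 }
      else {
        p <- p / sp
        H <- -sum(ifelse(p > 0, p * log(p), 0))
      }
      if (abs(H - target) < 1e-7) break
      if (H > target) {          # entropy too high: sharpen
        lo <- beta
        beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2
      } else {
        hi <- beta
        beta <- (beta + lo) / 2
      }
    }
    P[i, -i] <- p
  }
  P
}

#' Residual variance of an embedding
#'
#' `1 - r^2`, where `r` is the Pearson correlation between the upper-triangle
#' original distances and the pairwise Euclidean distances in the embedding.
#' For IsoMap embeddings the original distances are the graph geodesics (the
#' quantity IsoMap actually fits); for other methods the input distances `D`
#' are used. Values near 0 indicate the map reproduces the distance structure
#' faithfully; the statistic weakly decreases as embedding dimension grows.
#'
#' @param D `oct_dist` or symmetric matrix used to fit the embedding.
#' @param emb an `oct_embedding`.
#' @return Scalar in \[0, 1\].
#' @export
residual_variance <- function(D, emb) {
  D <- validate_dist_input(D)
  n <- nrow(D)
  if (n < 3L) stop("need at least 3 points")
  if (nrow(emb$coords) != n) stop("embedding size does not match D")
  ref <- if (identical(emb$method, "isomap") && !is.null(emb$geodesic))
    emb$geodesic else D
  ut <- upper.tri(ref)
  de <- as.matrix(stats::dist(emb$coords))
  r <- cor(ref[ut], de[ut])
  1 - r^2
}
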