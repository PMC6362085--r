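#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end run. Defaults follow the
#' method's stated values where one exists (median window 0.055 mm x
#' 0.117 mm, 2-D embedding) and documented package defaults otherwise
#' (diffusion `n_iter = 15`, `kappa = 0.1`, `lam = 0.25`; IsoMap `k = 12`;
#' t-SNE `perplexity = 30`, `seed = 0`).
#'
#' @param px_mm_x,px_mm_y pixel spacing of the input images (mm/px).
#' @param median_window_mm median filter window `c(h_mm, w_mm)`.
#' @param diffusion_iter,diffusion_kappa,diffusion_lam Perona-Malik
#'   parameters.
#' @param metric `"hellinger"` or `"euclidean"`.
#' @param method `"tsne"` or `"isomap"`.
#' @param isomap_k,perplexity embedding parameters. The pipeline default
#'   perplexity of 20 suits cohorts of around 100 images (t-SNE requires
#'   `perplexity < (n - 1) / 3`, and roughly `n / 5` anchors enough global
#'   structure for the direction statistic); raise it for larger datasets.
#' @param tsne_eta,tsne_exaggeration,tsne_exag_iter t-SNE optimizer settings
#'   (learning rate, `NULL` for the automatic rate; early-exaggeration
#'   factor and duration). The defaults favor a stable global arrangement
#'   over tight local cluster separation.
#' @param tsne_restarts number of seeded t-SNE restarts; the lowest-KL map
#'   is kept.
#' @param seed seed for the (stochastic) t-SNE stage.
#' @param grid_shape Image Map grid `c(rows, cols)`.
#' @param out_dir output directory for artifacts (`NULL` = no files).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(px_mm_x = 0.015625, px_mm_y = 0.03125,
                            median_window_mm = c(0.055, 0.117),
                            diffusion_iter = 15L, diffusion_kappa = 0.1,
                            diffusion_lam = 0.25,
                            metric = "hellinger", method = "tsne",
                            isomap_k = 12L, perplexity = 20,
                            tsne_eta = NULL, tsne_exaggeration = 4,
                            tsne_exag_iter = 250L, tsne_restarts = 5L,
                            seed = 0L,
                            grid_shape = c(6L, 10L), out_dir = NULL) {
  structure(list(
    px_mm_x = px_mm_x, px_mm_y = px_mm_y,
    median_window_mm = median_window_mm,
    diffusion_iter = diffusion_iter, diffusion_kappa = diffusion_kappa,
    diffusion_lam = diffusion_lam, metric = metric, method = method,
    isomap_k = isomap_k, perplexity = perplexity,
    tsne_eta = tsne_eta, tsne_exaggeration = tsne_exaggeration,
    tsne_exag_iter = tsne_exag_iter, tsne_restarts = tsne_restarts,
    seed = seed,
    grid_shape = grid_shape, out_dir = out_dir
  ), class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Unknown keys are rejected; missing keys take the [pipeline_config()]
#' defaults.
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(y), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  do.call(pipeline_config, y)
}

#' Write a pipeline configuration to YAML
#' @param config a `pipeline_config`.
#' @param path destination file.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Run the full unsupervised ordering pipeline
#'
#' Executes preprocess -> pairwise distance -> 2-D embedding (and, when
#' features are given, the best-direction correlations) on a directory of
#' PNG/TIFF images or an in-memory list of [gray_image]s. All randomness is
#' seeded from `config$seed`, so a rerun with the same config and inputs
#' reproduces the coordinates bit-identically. When `config$out_dir` is set,
#' aligned canvases (16-bit TIFF), the distance matrix, the coordinates and
#' a JSON manifest (config, config hash, per-stage counts) are written there.
#'
#' @param input directory path, or named list of [gray_image]s.
#' @param config a [pipeline_config()].
#' @param features optional data.frame of per-image features (rows in input
#'   order) to correlate with the embedding.
#' @return Invisibly, the run manifest: list with `config`, `config_hash`,
#'   `n_images`, `n_pairs`, `ids`, `aligned`, `D`, `embedding`, and
#'   `correlations` when features were supplied.
#' @export
run_pipeline <- function(input, config = pipeline_config(), features = NULL) {
  if (is.character(input)) {
    files <- sort(list.files(input, pattern = "\\.(png|tif|tiff)$",
                             ignore.case = TRUE, full.names = TRUE))
    if (!dir.exists(input)) stop("input directory does not exist: ", input)
    if (!length(files)) stop("input directory contains no PNG/TIFF images: ", input)
    imgs <- lapply(files, read_gray_image,
                   px_mm_x = config$px_mm_x, px_mm_y = config$px_mm_y)
    names(imgs) <- tools::file_path_sans_ext(basename(files))
  } else {
    imgs <- input
    if (!length(imgs)) stop("empty input image list")
    if (is.null(names(imgs))) names(imgs) <- sprintf("img_%03d", seq_along(imgs))
  }
  ids <- names(imgs)

  aligned <- vector("list", length(imgs))
  for (k in seq_along(imgs)) {
    aligned[[k]] <- tryCatch(
      preprocess_image(imgs[[k]], source_id = ids[k],
                       median_window_mm = config$median_window_mm,
                       diffusion_iter = config$diffusion_iter,
                       diffusion_kappa = config$diffusion_kappa,
                       diffusion_lam = config$diffusion_lam),
      error = function(e) stop("preprocess failed on image '", ids[k], "': ",
                               conditionMessage(e)))
  }
  names(aligned) <- ids

  D <- pairwise_distances(aligned, metric = config$metric, ids = ids)

  emb <- switch(config$method,
    tsne   = tsne_embed(D, perplexity = config$perplexity, seed = config$seed,
                        eta = config$tsne_eta,
                        exaggeration = config$tsne_exaggeration,
                        exag_iter = config$tsne_exag_iter,
                        n_restarts = config$tsne_restarts),
    isomap = isomap_embed(D, k = config$isomap_k),
    stop("unknown embedding method: ", config$method))

  corr <- if (!is.null(features)) correlation_table(emb, features) else NULL

  manifest <- list(
    config = unclass(config),
    config_hash = rlang::hash(unclass(config)),
    n_images = length(ids), n_pairs = attr(D, "n_pairs"),
    ids = ids, aligned = aligned, D = D, embedding = emb,
    correlations = corr
  )

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    for (id in ids)
      write_gray_image(aligned[[id]]$canvas,
                       file.path(config$out_dir, paste0(id, "_aligned.tiff")))
    write_distance_csv(D, file.path(config$out_dir, "D.csv"))
    write.csv(data.frame(id = ids, w = emb$coords[, 1], v = emb$coords[, 2]),
              file.path(config$out_dir, "coords.csv"), row.names = FALSE)
    write.csv(data.frame(
      source_id = ids,
      S = vapply(aligned, function(a) a$S, numeric(1)),
      rotation_deg = vapply(aligned, function(a) a$rotation_deg, numeric(1)),
      centroid_i = vapply(aligned, function(a) a$centroid[1], numeric(1)),
      centroid_j = vapply(aligned, function(a) a$centroid[2], numeric(1))),
      file.path(config$out_dir, "preprocess_manifest.csv"), row.names = FALSE)
    if (!is.null(corr))
      write.csv(corr, file.path(config$out_dir, "correlations.csv"),
                row.names = FALSE)
    jsonlite::write_json(
      list(config = unclass(config), config_hash = manifest$config_hash,
           n_images = manifest$n_images, n_pairs = manifest$n_pairs,
           ids = ids),
      file.path(config$out_dir, "manifest.json"), auto_unbox = TRUE,
      digits = NA, null = "null")
  }
  invisible(manifest)
}
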