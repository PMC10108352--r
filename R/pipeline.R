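## Config-driven orchestration: make-data, train-vqvae, train-density,
## segment, detect, evaluate. Every command writes its outputs plus a
## provenance JSON (config hash, seeds, package version) into a run
## directory and never mutates its inputs.

#' Default run configuration
#'
#' Nested configuration for the full pipeline, loadable from / writable to
#' YAML. Sections: `data` (synthetic generation or a directory source),
#' `vqvae`, `density` (ordering class and ensemble size), `healing`
#' (likelihood threshold, smoothing sigma, residual post-processing) and
#' `eval`.
#'
#' @param size Image shape.
#' @param seed Base seed; stages derive their own seeds from it.
#' @return Nested list of class `lh_config`.
#' @export
default_config <- function(size = c(64, 64), seed = 1) {
  nd <- length(size)
  structure(list(
    data = list(source = "synthetic", size = as.integer(size),
                n_train = 200L, n_val = 50L, n_test = 50L,
                intensities = c(0, 1), noise_sd = 0,
                normalization = if (nd == 2L) "minmax" else "percentile",
                seed = seed),
    vqvae = list(f = 8L, K = 32L, n_z = 64L, hidden = 128L, beta = 0.25,
                 decay = 0.99, epsilon = 1e-5, lr = 1e-3, epochs = 30L,
                 batch_size = 32L, seed = derive_seed(seed, 1)),
    density = list(ordering_class = "raster",
                   ensemble_size = if (nd == 2L) 8L else 7L,
                   context_order = 2L, alpha = 1,
                   seed = derive_seed(seed, 2)),
    healing = list(threshold = if (nd == 2L) 0.005 else 0.001,
                   sigma = NULL, positive_residuals = FALSE,
                   seed = derive_seed(seed, 3)),
    eval = list(residual_threshold = NULL)
  ), class = "lh_config")
}

#' Read / write a run configuration as YAML
#'
#' @param path YAML file path.
#' @return `read_config`: an `lh_config`; `write_config`: `path` invisibly.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- default_config(size = cfg$data$size %||% c(64, 64))
  for (sec in names(cfg)) {
    for (nm in names(cfg[[sec]])) base[[sec]][[nm]] <- cfg[[sec]][[nm]]
  }
  base
}

#' @rdname read_config
#' @param config An `lh_config`.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_provenance <- function(out_dir, stage, config, extra = list()) {
  prov <- c(list(
    stage = stage,
    config_hash = rlang::hash(config),
    package_version = as.character(utils::packageVersion("latentheal")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  ), extra)
  jsonlite::write_json(prov, file.path(out_dir, paste0(stage, "_provenance.json")),
                       auto_unbox = TRUE, pretty = TRUE)
}

#' Pipeline commands
#'
#' File-based orchestration over the in-memory API. `cmd_make_data` writes a
#' synthetic dataset; `cmd_train_vqvae` trains and checkpoints the VQ-VAE;
#' `cmd_train_density` trains one density model per ensemble ordering (it
#' requires the VQ-VAE checkpoint); `cmd_segment` writes residual maps and
#' binary masks; `cmd_detect` writes the detection table; `cmd_evaluate`
#' writes an evaluation report. Stage order is enforced through the
#' checkpoint arguments, and each stage writes a provenance JSON.
#'
#' @param config An `lh_config`.
#' @param out_dir Output/run directory.
#' @name pipeline
NULL

#' @rdname pipeline
#' @export
cmd_make_data <- function(config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  d <- config$data
  manifest <- make_synthetic_dataset(
    out_dir, n_train = d$n_train, n_val = d$n_val, n_test = d$n_test,
    size = d$size, seed = d$seed, intensities = d$intensities,
    noise_sd = d$noise_sd)
  write_provenance(out_dir, "make_data", config,
                   list(n_samples = nrow(manifest)))
  invisible(manifest)
}

load_split <- function(data_dir, split, normalization = "none") {
  manifest <- utils::read.csv(file.path(data_dir, "manifest.csv"),
                              stringsAsFactors = FALSE)
  rows <- manifest[manifest$split == split, ]
  images <- lapply(file.path(data_dir, rows$file), read_image,
                   normalize = normalization)
  gt <- lapply(seq_len(nrow(rows)), function(i) {
    if (is.na(rows$gt_file[i])) NULL
    else (read_image(file.path(data_dir, rows$gt_file[i])) > 0.5) * 1L
  })
  list(images = images, gt = gt, manifest = rows)
}

#' @rdname pipeline
#' @param data_dir Dataset directory produced by `cmd_make_data`.
#' @export
cmd_train_vqvae <- function(config, data_dir, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tr <- load_split(data_dir, "train", config$data$normalization)
  v <- config$vqvae
  cfg <- vqvae_config(input_shape = config$data$size, f = v$f, K = v$K,
                      n_z = v$n_z, hidden = v$hidden, beta = v$beta,
                      decay = v$decay, epsilon = v$epsilon, lr = v$lr,
                      epochs = v$epochs, batch_size = v$batch_size,
                      seed = v$seed)
  model <- train_vqvae(tr$images, cfg)
  saveRDS(model, file.path(out_dir, "vqvae.rds"))
  utils::write.csv(model$log, file.path(out_dir, "vqvae_log.csv"),
                   row.names = FALSE)
  write_provenance(out_dir, "train_vqvae", config,
                   list(n_train = length(tr$images)))
  invisible(model)
}

#' @rdname pipeline
#' @param vqvae_path Path to the VQ-VAE checkpoint (`vqvae.rds`).
#' @export
cmd_train_density <- function(config, vqvae_path, data_dir, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  vq <- readRDS(vqvae_path)
  stopifnot(inherits(vq, "lh_vqvae"))
  tr <- load_split(data_dir, "train", config$data$normalization)
  dn <- config$density
  orderings <- ensemble_orderings(dn$ordering_class,
                                  latent_shape(vq$config),
                                  count = dn$ensemble_size, seed = dn$seed)
  members <- lapply(seq_along(orderings), function(i) {
    o <- orderings[[i]]
    seqs <- lapply(tr$images, image_tokens, vqvae = vq, ordering = o)
    dens <- train_density_model(seqs, K = vq$config$K, ordering = o,
                                context_order = dn$context_order,
                                alpha = dn$alpha,
                                seed = derive_seed(dn$seed, i))
    list(density = dens, ordering = o)
  })
  saveRDS(members, file.path(out_dir, "density_ensemble.rds"))
  write_provenance(out_dir, "train_density", config,
                   list(n_members = length(members)))
  invisible(members)
}

load_members <- function(path) {
  members <- readRDS(path)
  stopifnot(is.list(members), length(members) >= 1L)
  members
}

#' @rdname pipeline
#' @param density_path Path to the density ensemble checkpoint.
#' @param inputs Character vector of image paths, or a dataset directory
#'   (its test split is used).
#' @export
cmd_segment <- function(config, vqvae_path, density_path, inputs, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  vq <- readRDS(vqvae_path)
  members <- load_members(density_path)
  h <- config$healing
  if (length(inputs) == 1L && dir.exists(inputs)) {
    split <- load_split(inputs, "test", config$data$normalization)
    images <- split$images
    ids <- split$manifest$id
  } else {
    images <- lapply(inputs, read_image,
                     normalize = config$data$normalization)
    ids <- tools::file_path_sans_ext(basename(inputs))
  }
  ext <- if (length(config$data$size) == 2L) ".png" else ".nii.gz"
  for (i in seq_along(images)) {
    seg <- segment_ensemble(images[[i]], vq, members,
                            threshold = h$threshold, sigma = h$sigma,
                            rng_seed = derive_seed(h$seed, i),
                            positive_residuals = isTRUE(h$positive_residuals))
    res <- seg$residual
    write_image(res / max(max(res), 1e-12),
                file.path(out_dir, paste0(ids[i], "_residual", ext)))
    if (!is.null(config$eval$residual_threshold)) {
      write_image(binarize(res, config$eval$residual_threshold),
                  file.path(out_dir, paste0(ids[i], "_mask", ext)))
    }
    saveRDS(res, file.path(out_dir, paste0(ids[i], "_residual.rds")))
  }
  write_provenance(out_dir, "segment", config, list(n_images = length(images)))
  invisible(ids)
}

#' @rdname pipeline
#' @export
cmd_detect <- function(config, vqvae_path, density_path, inputs, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  vq <- readRDS(vqvae_path)
  members <- load_members(density_path)
  if (length(inputs) == 1L && dir.exists(inputs)) {
    split <- load_split(inputs, "test", config$data$normalization)
    images <- split$images
    ids <- split$manifest$id
  } else {
    images <- lapply(inputs, read_image,
                     normalize = config$data$normalization)
    ids <- tools::file_path_sans_ext(basename(inputs))
  }
  tab <- detect_images(images, vq, members,
                       residual_threshold = config$eval$residual_threshold,
                       threshold = config$healing$threshold,
                       sigma = config$healing$sigma,
                       rng_seed = config$healing$seed, ids = ids)
  utils::write.csv(tab, file.path(out_dir, "detection.csv"),
                   row.names = FALSE)
  write_provenance(out_dir, "detect", config, list(n_images = nrow(tab)))
  invisible(tab)
}

#' @rdname pipeline
#' @param residual_dir Directory of `*_residual.rds` maps from `cmd_segment`.
#' @param gt_dir Dataset directory holding the ground-truth masks.
#' @export
cmd_evaluate <- function(config, residual_dir, gt_dir, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  split <- load_split(gt_dir, "test", "none")
  have_gt <- !vapply(split$gt, is.null, TRUE)
  if (!any(have_gt)) {
    stop("evaluation requires ground-truth masks; the test split of ",
         gt_dir, " has none")
  }
  ids <- split$manifest$id[have_gt]
  residuals <- lapply(ids, function(id) {
    p <- file.path(residual_dir, paste0(id, "_residual.rds"))
    if (!file.exists(p)) stop("missing residual map for sample ", id)
    readRDS(p)
  })
  report <- eval_report(residuals, split$gt[have_gt])
  jsonlite::write_json(as.list(report), file.path(out_dir, "eval_report.json"),
                       auto_unbox = TRUE, digits = NA)
  utils::write.csv(report, file.path(out_dir, "eval_report.csv"),
                   row.names = FALSE)
  write_provenance(out_dir, "evaluate", config, list(n_images = length(ids)))
  report
}
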