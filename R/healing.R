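## Latent healing: threshold token likelihoods into a resampling mask,
## resample masked tokens autoregressively, decode the healed sequence, and
## filter the pixel residuals by the upsampled, Gaussian-smoothed mask.

#' Resampling mask from a likelihood profile
#'
#' Marks token `i` anomalous iff `p_i <= threshold` (ties count as
#' anomalous). Defaults: 0.005 for 2D, 0.001 for 3D latent grids.
#'
#' @param profile An `lh_likelihood` (or a bare probability vector).
#' @param threshold Scalar in (0, 1).
#' @return List of class `lh_resampling_mask` with binary `m` and
#'   `threshold`.
#' @export
resampling_mask <- function(profile, threshold = 0.005) {
  stopifnot(threshold > 0, threshold < 1)
  p <- if (inherits(profile, "lh_likelihood")) profile$p else profile
  structure(list(m = as.integer(p <= threshold), threshold = threshold),
            class = "lh_resampling_mask")
}

#' Heal a token sequence by conditional resampling
#'
#' Unmasked positions are copied verbatim. Masked positions are resampled
#' left to right from the model's next-token distribution conditioned on the
#' already-healed prefix, so earlier replacements inform later ones.
#'
#' @param model An `lh_density`.
#' @param tokens Observed token sequence.
#' @param mask An `lh_resampling_mask` (or binary vector) of the same length.
#' @param rng_seed Integer seed for the resampling draws.
#' @param temperature Sampling temperature.
#' @return Healed integer token sequence.
#' @export
heal_sequence <- function(model, tokens, mask, rng_seed = 0,
                          temperature = 1) {
  m <- if (inherits(mask, "lh_resampling_mask")) mask$m else as.integer(mask)
  check_sequence(model, tokens)
  stopifnot(length(m) == length(tokens))
  healed <- as.integer(tokens)
  if (!any(m == 1L)) return(healed)
  with_seed(rng_seed, {
    for (i in which(m == 1L)) {
      ctx <- context_at(model, healed, i)
      p <- backoff_distribution(model, i, ctx)
      healed[i] <- sample_next(p, temperature)
    }
    healed
  })
}

#' Pixel-wise residual map
#'
#' Absolute residuals `|x - x_healed|` by default; with `signed = TRUE` the
#' positive part `max(x - x_healed, 0)` only, the post-processing used for
#' hyperintense lesions.
#'
#' @param x Input image.
#' @param x_healed Healed reconstruction (same shape).
#' @param signed Use the positive-residual post-processing mode.
#' @return Non-negative array of the same shape.
#' @export
residual_map <- function(x, x_healed, signed = FALSE) {
  stopifnot(all(img_dim(x) == img_dim(x_healed)))
  if (signed) pmax(x - x_healed, 0) else abs(x - x_healed)
}

#' Project a resampling mask into image space
#'
#' The 1D mask is mapped back onto the latent grid with the ordering's
#' inverse, upsampled by nearest-neighbour replication to image resolution,
#' Gaussian-smoothed, and clipped to \[0,1\].
#'
#' @param mask An `lh_resampling_mask` (or binary vector).
#' @param ordering The `lh_ordering` the sequence was produced under.
#' @param image_shape Target image shape (each latent cell becomes an
#'   `f^ndim` patch, `f = image_shape / grid_shape`).
#' @param sigma Gaussian smoothing s.d. in pixels (default `f / 2`).
#' @return Array of shape `image_shape`, values in \[0,1\].
#' @export
latent_mask_to_image_mask <- function(mask, ordering, image_shape,
                                      sigma = NULL) {
  m <- if (inherits(mask, "lh_resampling_mask")) mask$m else as.integer(mask)
  grid <- invert_ordering(m, ordering)
  f <- unique(as.integer(image_shape) %/% ordering$shape)
  if (length(f) != 1L || any(as.integer(image_shape) %% ordering$shape != 0)) {
    stop("image_shape must be an integer multiple of the latent grid shape")
  }
  if (is.null(sigma)) sigma <- f / 2
  up <- upsample_nearest(grid, f)
  clip01(gaussian_smooth(up, sigma))
}

#' Filter a residual map by an image-space mask
#'
#' Elementwise product; the filtered residual never exceeds the input.
#'
#' @param residual Residual map.
#' @param image_mask Array in \[0,1\] of the same shape.
#' @return Masked residual map.
#' @export
masked_residual <- function(residual, image_mask) {
  stopifnot(all(img_dim(residual) == img_dim(image_mask)))
  residual * image_mask
}

#' Binarize a residual map
#'
#' Pixels strictly above the threshold are marked anomalous.
#'
#' @param residual Residual map.
#' @param threshold Scalar threshold.
#' @return Binary integer array.
#' @export
binarize <- function(residual, threshold) {
  (residual > threshold) * 1L
}

#' Segment one image with a single density model
#'
#' The full chain: encode, quantize, order, teacher-forced likelihoods on the
#' original sequence, resampling mask, healing, inverse ordering, decode,
#' residuals, latent-mask filtering.
#'
#' @param image Input image (already normalized to \[0,1\]).
#' @param vqvae An `lh_vqvae`.
#' @param density An `lh_density` trained under `ordering`.
#' @param ordering The matching `lh_ordering`.
#' @param threshold Resampling-mask likelihood threshold.
#' @param sigma Gaussian smoothing s.d. for the image-space mask
#'   (default `f / 2`).
#' @param rng_seed Seed for the healing draws.
#' @param positive_residuals Use the positive-part residual post-processing.
#' @return List of class `lh_segmentation`: `residual` (mask-filtered),
#'   `residual_raw` (unfiltered healed residual), `healed_image`,
#'   `resampling_mask`, `image_mask`, `tokens`, `healed_tokens`.
#' @export
segment_single <- function(image, vqvae, density, ordering,
                           threshold = 0.005, sigma = NULL, rng_seed = 0,
                           positive_residuals = FALSE) {
  check_ordering_match(density, ordering)
  lat <- encode(vqvae, image)
  tokens <- apply_ordering(lat$indices, ordering)
  prof <- sequence_likelihood(density, tokens, ordering)
  rmask <- resampling_mask(prof, threshold)
  healed_tokens <- heal_sequence(density, tokens, rmask, rng_seed = rng_seed)
  healed_grid <- invert_ordering(healed_tokens, ordering)
  healed_image <- decode(vqvae, indices = healed_grid)
  res <- residual_map(image, healed_image, signed = positive_residuals)
  imask <- latent_mask_to_image_mask(rmask, ordering, img_dim(image), sigma)
  structure(list(residual = masked_residual(res, imask),
                 residual_raw = res,
                 healed_image = healed_image,
                 resampling_mask = rmask,
                 image_mask = imask,
                 tokens = tokens,
                 healed_tokens = healed_tokens,
                 likelihood = prof),
            class = "lh_segmentation")
}

#' Segment one image with an ordering ensemble
#'
#' Each (density model, ordering) member independently heals and produces its
#' own mask-filtered residual map; the ensemble residual is their elementwise
#' mean.
#'
#' @param image Input image.
#' @param vqvae An `lh_vqvae`.
#' @param members List of `list(density = , ordering = )` pairs.
#' @param threshold,sigma,rng_seed,positive_residuals As [segment_single()];
#'   each member heals under a seed derived from `rng_seed`.
#' @param keep_members Keep the per-member `lh_segmentation`s.
#' @return List of class `lh_segmentation_ensemble` with `residual` (mean
#'   map) and optionally `members`.
#' @export
segment_ensemble <- function(image, vqvae, members, threshold = 0.005,
                             sigma = NULL, rng_seed = 0,
                             positive_residuals = FALSE,
                             keep_members = FALSE) {
  stopifnot(length(members) >= 1L)
  segs <- lapply(seq_along(members), function(i) {
    segment_single(image, vqvae, members[[i]]$density, members[[i]]$ordering,
                   threshold = threshold, sigma = sigma,
                   rng_seed = derive_seed(rng_seed, i),
                   positive_residuals = positive_residuals)
  })
  mean_res <- Reduce(`+`, lapply(segs, `[[`, "residual")) / length(segs)
  structure(list(residual = mean_res,
                 members = if (keep_members) segs else NULL,
                 n_members = length(segs)),
            class = "lh_segmentation_ensemble")
}
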