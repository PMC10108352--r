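## Image-wise anomaly detection: ensemble-mean sequence log-likelihood and a
## two-feature (log-likelihood, lesion volume) one-class decision rule.

#' Image-wise log-likelihood under an ordering ensemble
#'
#' Each member scores the same latent grid under its own ordering; the
#' image-wise score is `log p(x) = sum_i log p(s_i)` per member and the
#' arithmetic mean over members.
#'
#' @param image Input image.
#' @param vqvae An `lh_vqvae`.
#' @param members List of `list(density = , ordering = )` pairs.
#' @return List of class `lh_detection_score` with `per_model_logp` and
#'   `mean_logp`.
#' @export
image_log_likelihood <- function(image, vqvae, members) {
  stopifnot(length(members) >= 1L)
  lat <- encode(vqvae, image)
  logps <- vapply(members, function(mem) {
    check_ordering_match(mem$density, mem$ordering)
    tokens <- apply_ordering(lat$indices, mem$ordering)
    sequence_likelihood(mem$density, tokens, mem$ordering)$logp_total
  }, 0)
  structure(list(per_model_logp = logps, mean_logp = mean(logps)),
            class = "lh_detection_score")
}

#' Lesion volume of a binary segmentation mask
#'
#' @param mask Binary array (pixels/voxels marked anomalous).
#' @return Integer count of set elements.
#' @export
lesion_volume <- function(mask) {
  as.integer(sum(mask > 0))
}

#' Fit a one-class scorer on reference (normal) feature vectors
#'
#' Standardizes the features and fits a one-class support vector machine on
#' validation images assumed normal. Higher scores mean "more normal"
#' (reference-like); anomalous images score lower.
#'
#' @param features Data frame / tibble of numeric features from normal
#'   validation images (e.g. columns `mean_logp`, `lesion_volume`); at least
#'   10 rows.
#' @param nu One-class SVM `nu` parameter.
#' @param gamma RBF kernel width; default `1 / n_features`.
#' @return Object of class `lh_ocsvm`.
#' @export
fit_one_class_scorer <- function(features, nu = 0.1, gamma = NULL) {
  X <- as.matrix(as.data.frame(features))
  if (nrow(X) < 10L) {
    stop("need at least 10 reference feature points to fit the one-class ",
         "scorer, got ", nrow(X))
  }
  mu <- colMeans(X)
  sd_ <- apply(X, 2, stats::sd)
  sd_[sd_ == 0] <- 1
  Xs <- sweep(sweep(X, 2, mu, `-`), 2, sd_, `/`)
  if (is.null(gamma)) gamma <- 1 / ncol(Xs)
  fit <- e1071::svm(Xs, y = NULL, type = "one-classification",
                    kernel = "radial", nu = nu, gamma = gamma,
                    scale = FALSE)
  structure(list(fit = fit, center = mu, scale = sd_,
                 features = colnames(X)),
            class = "lh_ocsvm")
}

#' Score feature vectors with a fitted one-class scorer
#'
#' @param scorer An `lh_ocsvm`.
#' @param features Data frame with the same feature columns.
#' @return Numeric vector of decision scores (higher = more normal).
#' @export
score_one_class <- function(scorer, features) {
  stopifnot(inherits(scorer, "lh_ocsvm"))
  X <- as.matrix(as.data.frame(features)[, scorer$features, drop = FALSE])
  Xs <- sweep(sweep(X, 2, scorer$center, `-`), 2, scorer$scale, `/`)
  pred <- stats::predict(scorer$fit, Xs, decision.values = TRUE)
  as.numeric(attr(pred, "decision.values"))
}

#' Detection table for a set of images
#'
#' Computes per-image per-member log-likelihoods, the ensemble mean, and
#' (optionally) the predicted lesion volume from ensemble segmentation.
#'
#' @param images List of images.
#' @param vqvae An `lh_vqvae`.
#' @param members Ensemble members.
#' @param residual_threshold If not `NULL`, run ensemble segmentation and
#'   binarize at this threshold to obtain `lesion_volume`.
#' @param threshold,sigma,rng_seed Segmentation parameters (see
#'   [segment_ensemble()]).
#' @param ids Optional image identifiers.
#' @return Tibble, one row per image: `id`, `mean_logp`, one
#'   `logp_<k>` column per member, and `lesion_volume` when computed.
#' @export
detect_images <- function(images, vqvae, members, residual_threshold = NULL,
                          threshold = 0.005, sigma = NULL, rng_seed = 0,
                          ids = NULL) {
  if (is.null(ids)) ids <- sprintf("img_%04d", seq_along(images))
  rows <- lapply(seq_along(images), function(i) {
    sc <- image_log_likelihood(images[[i]], vqvae, members)
    row <- tibble::tibble(id = ids[i], mean_logp = sc$mean_logp)
    for (k in seq_along(sc$per_model_logp)) {
      row[[paste0("logp_", k)]] <- sc$per_model_logp[k]
    }
    if (!is.null(residual_threshold)) {
      seg <- segment_ensemble(images[[i]], vqvae, members,
                              threshold = threshold, sigma = sigma,
                              rng_seed = derive_seed(rng_seed, i))
      row$lesion_volume <- lesion_volume(binarize(seg$residual,
                                                  residual_threshold))
    }
    row
  })
  do.call(rbind, rows)
}
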