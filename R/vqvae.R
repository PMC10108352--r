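## Vector-quantized autoencoder over non-overlapping patches.
##
## The encoder maps each f x f (x f) patch to an encoding of the same
## dimension through a pixel-anchored residual MLP, Z = P + MLP(P), whose
## output layer starts at zero: the encoder begins as the identity and
## learns only the warp that helps reconstruction. The quantizer snaps each
## encoding to the nearest codebook vector (squared Euclidean, ties to the
## lowest index); the decoder maps the quantized vector back to a patch
## through an MLP with a sigmoid output. Training uses the straight-through
## estimator for the quantizer and exponential-moving-average codebook
## updates in place of the codebook loss term, with the commitment term
## weighted by beta. By default the encoder warp is disabled
## (encoder_warp = FALSE): the encoder stays at the identity embedding and
## the codebook is learned purely by EMA (online k-means in pixel space).
## Rationale: a warp trained with the commitment objective contracts the
## encoding space toward the codebook, which collapses unseen anomalous
## patches onto common codes and hides them from the downstream density
## models; the identity embedding keeps them separated. Working on disjoint
## patches makes latent-space translation consistency exact: shifting the
## image by f pixels shifts the index grid by one cell.

#' Default VQ-VAE configuration
#'
#' @param input_shape Image shape the model is built for.
#' @param f Spatial downsampling factor per axis (latent grid =
#'   `input_shape / f`).
#' @param K Codebook size (vocabulary).
#' @param n_z Dimensionality of each latent embedding vector; the residual
#'   pixel anchoring ties it to the patch size, so it is always
#'   `f^ndim` (a different request is rejected).
#' @param hidden Hidden width of the patch encoder/decoder MLPs.
#' @param beta Commitment loss weight.
#' @param decay EMA decay for codebook updates.
#' @param epsilon Laplace smoothing constant for EMA cluster sizes.
#' @param lr Adam learning rate.
#' @param epochs,batch_size Training schedule.
#' @param val_frac Held-out fraction for the training log.
#' @param encoder_warp Train the residual encoder MLP. Default `FALSE`
#'   (identity encoder): a learned warp, pulled toward the codebook by the
#'   commitment term, generalizes that pull to unseen anomalous patches and
#'   "heals" them during encoding, which suppresses the latent anomaly
#'   signal the density ensemble needs.
#' @param seed RNG seed controlling initialization and batching.
#' @return A list of class `lh_vqvae_config`.
#' @export
vqvae_config <- function(input_shape = c(64, 64), f = 8, K = 32, n_z = NULL,
                         hidden = 128, beta = 0.25, decay = 0.99,
                         epsilon = 1e-5, lr = 1e-3, epochs = 30,
                         batch_size = 32, val_frac = 0.1,
                         encoder_warp = FALSE, seed = 1) {
  input_shape <- as.integer(input_shape)
  if (any(input_shape %% f != 0)) {
    stop("input_shape must be divisible by f in every dimension")
  }
  p <- as.integer(f)^length(input_shape)
  if (is.null(n_z)) n_z <- p
  if (n_z != p) {
    stop("the pixel-anchored encoder requires n_z = f^ndim = ", p)
  }
  structure(list(input_shape = input_shape, f = as.integer(f),
                 K = as.integer(K), n_z = as.integer(n_z),
                 hidden = as.integer(hidden), beta = beta, decay = decay,
                 epsilon = epsilon, lr = lr, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), val_frac = val_frac,
                 encoder_warp = isTRUE(encoder_warp), seed = seed),
            class = "lh_vqvae_config")
}

latent_shape <- function(config) config$input_shape %/% config$f

## ---- patch bookkeeping ----------------------------------------------------

## Rows = patches in latent-grid column-major order, columns = pixels.
image_to_patches <- function(x, f) {
  d <- img_dim(x)
  g <- d %/% f
  if (length(d) == 2L) {
    blocks <- matrix(0, prod(g), f * f)
    k <- 0L
    for (j in seq_len(g[2])) for (i in seq_len(g[1])) {
      k <- k + 1L
      blocks[k, ] <- as.vector(x[(i - 1L) * f + seq_len(f),
                                 (j - 1L) * f + seq_len(f)])
    }
    blocks
  } else {
    blocks <- matrix(0, prod(g), f^3)
    k <- 0L
    for (l in seq_len(g[3])) for (j in seq_len(g[2])) for (i in seq_len(g[1])) {
      k <- k + 1L
      blocks[k, ] <- as.vector(x[(i - 1L) * f + seq_len(f),
                                 (j - 1L) * f + seq_len(f),
                                 (l - 1L) * f + seq_len(f)])
    }
    blocks
  }
}

patches_to_image <- function(p, shape, f) {
  g <- shape %/% f
  x <- array(0, shape)
  k <- 0L
  if (length(shape) == 2L) {
    for (j in seq_len(g[2])) for (i in seq_len(g[1])) {
      k <- k + 1L
      x[(i - 1L) * f + seq_len(f), (j - 1L) * f + seq_len(f)] <-
        matrix(p[k, ], f, f)
    }
  } else {
    for (l in seq_len(g[3])) for (j in seq_len(g[2])) for (i in seq_len(g[1])) {
      k <- k + 1L
      x[(i - 1L) * f + seq_len(f), (j - 1L) * f + seq_len(f),
        (l - 1L) * f + seq_len(f)] <- array(p[k, ], c(f, f, f))
    }
  }
  x
}

## ---- codebook -------------------------------------------------------------

new_codebook <- function(K, n_z, decay = 0.99, epsilon = 1e-5,
                         init = NULL) {
  vectors <- if (is.null(init)) {
    matrix(stats::rnorm(K * n_z, sd = 0.1), K, n_z)
  } else {
    stopifnot(all(dim(init) == c(K, n_z)))
    ## jitter so duplicated initializers still separate
    init + matrix(stats::rnorm(K * n_z, sd = 0.01), K, n_z)
  }
  structure(list(vectors = vectors,
                 ema_cluster_size = rep(1, K),
                 ema_embedding_sum = vectors,
                 decay = decay, epsilon = epsilon),
            class = "lh_codebook")
}

#' Quantize encodings against a codebook
#'
#' Each encoding row is assigned the squared-Euclidean nearest codebook
#' vector; ties break toward the lowest index.
#'
#' @param encodings Numeric matrix (rows = latent positions) or an array of
#'   shape `c(grid, n_z)`.
#' @param codebook An `lh_codebook` (or a plain K x n_z matrix).
#' @return List with `indices` (integer vector/grid in `1..K`) and
#'   `quantized` (same shape as `encodings`).
#' @export
quantize <- function(encodings, codebook) {
  E <- if (inherits(codebook, "lh_codebook")) codebook$vectors else codebook
  grid_dim <- NULL
  Z <- encodings
  if (!is.null(dim(Z)) && length(dim(Z)) > 2L) {
    d <- dim(Z)
    grid_dim <- d[-length(d)]
    Z <- matrix(Z, prod(grid_dim), d[length(d)])
  }
  if (is.null(dim(Z))) Z <- matrix(Z, 1)
  if (!all(is.finite(Z))) stop("non-finite encodings passed to quantize()")
  ## squared distances via the expansion |z|^2 - 2 z.e + |e|^2
  d2 <- outer(rowSums(Z^2), rep(1, nrow(E))) - 2 * Z %*% t(E) +
    outer(rep(1, nrow(Z)), rowSums(E^2))
  idx <- max.col(-d2, ties.method = "first")
  Q <- E[idx, , drop = FALSE]
  if (!is.null(grid_dim)) {
    idx <- array(idx, grid_dim)
    Q <- array(Q, c(grid_dim, ncol(E)))
  }
  list(indices = idx, quantized = Q)
}

#' One exponential-moving-average codebook update
#'
#' Cluster sizes and embedding sums are decayed accumulators over assigned
#' encodings; codebook vectors become the smoothed sum divided by the
#' Laplace-smoothed cluster size. With EMA active no gradient touches the
#' codebook.
#'
#' @param codebook An `lh_codebook`.
#' @param encodings Matrix of encodings (rows = positions in the batch).
#' @param indices Integer vector of current nearest assignments.
#' @return The updated `lh_codebook`.
#' @export
ema_update <- function(codebook, encodings, indices) {
  stopifnot(inherits(codebook, "lh_codebook"))
  K <- nrow(codebook$vectors)
  idx <- as.integer(indices)
  counts <- tabulate(idx, nbins = K)
  sums <- matrix(0, K, ncol(codebook$vectors))
  present <- sort(unique(idx))
  for (k in present) {
    sums[k, ] <- colSums(encodings[idx == k, , drop = FALSE])
  }
  d <- codebook$decay
  codebook$ema_cluster_size <- d * codebook$ema_cluster_size + (1 - d) * counts
  codebook$ema_embedding_sum <- d * codebook$ema_embedding_sum + (1 - d) * sums
  n <- sum(codebook$ema_cluster_size)
  smoothed <- (codebook$ema_cluster_size + codebook$epsilon) /
    (n + K * codebook$epsilon) * n
  codebook$vectors <- codebook$ema_embedding_sum / smoothed
  codebook
}

#' VQ-VAE loss terms
#'
#' Per-pixel/per-element mean reductions: `recons` is the mean squared
#' reconstruction error, `commit` the mean squared distance between the
#' encodings and their (detached) codebook vectors. The codebook term is zero
#' when EMA updates are active (the default), mirroring its replacement by
#' the moving-average update.
#'
#' @param x,x_hat Input and reconstruction (same shape).
#' @param encodings,quantized Encoder outputs and their quantized values.
#' @param beta Commitment weight.
#' @param ema Whether EMA codebook updates replace the codebook loss term.
#' @return List with `recons`, `codebook_term`, `commit`, `beta`, `total`.
#' @export
vqvae_loss <- function(x, x_hat, encodings, quantized, beta = 0.25,
                       ema = TRUE) {
  stopifnot(all(img_dim(x) == img_dim(x_hat)),
            length(encodings) == length(quantized))
  recons <- mean((x - x_hat)^2)
  commit <- mean((encodings - quantized)^2)
  codebook_term <- if (ema) 0 else commit
  list(recons = recons, codebook_term = codebook_term, commit = commit,
       beta = beta, total = recons + codebook_term + beta * commit)
}

## ---- forward / backward ---------------------------------------------------

init_params <- function(p, hidden, n_z) {
  g <- function(nr, nc) matrix(stats::rnorm(nr * nc, sd = sqrt(2 / nr)), nr, nc)
  ## W2/b2 start at zero: the encoder begins as the identity map
  list(W1 = g(p, hidden), b1 = rep(0, hidden),
       W2 = matrix(0, hidden, n_z), b2 = rep(0, n_z),
       W3 = g(n_z, hidden), b3 = rep(0, hidden),
       W4 = g(hidden, p), b4 = rep(0, p))
}

encoder_forward <- function(params, P) {
  H1 <- tanh(sweep(P %*% params$W1, 2, params$b1, `+`))
  Z <- P + sweep(H1 %*% params$W2, 2, params$b2, `+`)
  list(H1 = H1, Z = Z)
}

decoder_forward <- function(params, Q) {
  H2 <- tanh(sweep(Q %*% params$W3, 2, params$b3, `+`))
  A <- sweep(H2 %*% params$W4, 2, params$b4, `+`)
  Xhat <- 1 / (1 + exp(-A))
  list(H2 = H2, Xhat = Xhat)
}

## Full training step gradients (straight-through at the quantizer:
## d quantized / d encodings = identity).
vqvae_gradients <- function(params, P, codebook, beta) {
  enc <- encoder_forward(params, P)
  q <- quantize(enc$Z, codebook)
  dec <- decoder_forward(params, q$quantized)
  n_el <- length(P)
  n_z_el <- length(enc$Z)

  dXhat <- 2 * (dec$Xhat - P) / n_el
  dA4 <- dXhat * dec$Xhat * (1 - dec$Xhat)
  dW4 <- t(dec$H2) %*% dA4
  db4 <- colSums(dA4)
  dH2 <- dA4 %*% t(params$W4)
  dA3 <- dH2 * (1 - dec$H2^2)
  dW3 <- t(q$quantized) %*% dA3
  db3 <- colSums(dA3)
  dQ <- dA3 %*% t(params$W3)
  dZ <- dQ + 2 * beta * (enc$Z - q$quantized) / n_z_el  # straight-through
  ## residual encoder: Z = P + H1 W2 + b2
  dW2 <- t(enc$H1) %*% dZ
  db2 <- colSums(dZ)
  dH1 <- dZ %*% t(params$W2)
  dA1 <- dH1 * (1 - enc$H1^2)
  dW1 <- t(P) %*% dA1
  db1 <- colSums(dA1)

  list(grads = list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2,
                    W3 = dW3, b3 = db3, W4 = dW4, b4 = db4),
       encodings = enc$Z, indices = q$indices, quantized = q$quantized,
       Xhat = dec$Xhat)
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(params)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grads[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    mh <- state$m[[nm]] / (1 - beta1^state$t)
    vh <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mh / (sqrt(vh) + eps)
  }
  list(params = params, state = state)
}

## ---- public model API -----------------------------------------------------

#' Train a VQ-VAE on a set of normal images
#'
#' @param images List of numeric arrays, all of the configured input shape,
#'   intensities in \[0,1\].
#' @param config An [vqvae_config()] list.
#' @return An object of class `lh_vqvae`: parameters, codebook, config and a
#'   per-epoch training log (tibble with train/validation reconstruction and
#'   commitment losses).
#' @export
train_vqvae <- function(images, config = vqvae_config()) {
  stopifnot(length(images) >= 2L)
  for (x in images) {
    if (!all(img_dim(x) == config$input_shape)) {
      stop("image shape ", paste(img_dim(x), collapse = "x"),
           " does not match configured input shape ",
           paste(config$input_shape, collapse = "x"))
    }
  }
  p <- config$f^length(config$input_shape)
  with_seed(config$seed, {
    params <- init_params(p, config$hidden, config$n_z)
    n <- length(images)
    n_val <- max(1L, round(config$val_frac * n))
    shuffled <- sample.int(n)
    val_ids <- shuffled[seq_len(n_val)]
    train_ids <- shuffled[-seq_len(n_val)]
    P_val <- do.call(rbind, lapply(images[val_ids],
                                   image_to_patches, f = config$f))
    P_all <- lapply(images[train_ids], image_to_patches, f = config$f)
    ## codebook initialized from random training patches (k-means style)
    pool <- do.call(rbind, P_all[sample.int(length(P_all),
                                            min(20L, length(P_all)))])
    codebook <- new_codebook(config$K, config$n_z, config$decay,
                             config$epsilon,
                             init = pool[sample.int(nrow(pool), config$K), ,
                                         drop = FALSE])
    opt <- adam_init(params)
    log <- vector("list", config$epochs)

    eval_loss <- function(P) {
      enc <- encoder_forward(params, P)
      q <- quantize(enc$Z, codebook)
      dec <- decoder_forward(params, q$quantized)
      c(recons = mean((P - dec$Xhat)^2),
        commit = mean((enc$Z - q$quantized)^2))
    }

    for (epoch in seq_len(config$epochs)) {
      ord <- sample.int(length(P_all))
      batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
      tr_rec <- tr_com <- 0
      for (b in batches) {
        P <- do.call(rbind, P_all[b])
        g <- vqvae_gradients(params, P, codebook, config$beta)
        if (!config$encoder_warp) {
          for (nm in c("W1", "b1", "W2", "b2")) g$grads[[nm]][] <- 0
        }
        step <- adam_step(params, g$grads, opt, config$lr)
        params <- step$params
        opt <- step$state
        codebook <- ema_update(codebook, g$encodings, g$indices)
        rec <- mean((P - g$Xhat)^2)
        if (!is.finite(rec)) {
          stop("VQ-VAE training diverged (non-finite loss) at epoch ", epoch)
        }
        tr_rec <- tr_rec + rec * length(b)
        tr_com <- tr_com + mean((g$encodings - g$quantized)^2) * length(b)
      }
      vl <- eval_loss(P_val)
      log[[epoch]] <- tibble::tibble(
        epoch = epoch,
        train_recons = tr_rec / length(P_all),
        train_commit = tr_com / length(P_all),
        val_recons = vl["recons"], val_commit = vl["commit"])
    }
    structure(list(params = params, codebook = codebook, config = config,
                   log = do.call(rbind, log)),
              class = "lh_vqvae")
  })
}

#' @export
print.lh_vqvae <- function(x, ...) {
  cat("<lh_vqvae> input", paste(x$config$input_shape, collapse = "x"),
      "f =", x$config$f, "K =", x$config$K, "n_z =", x$config$n_z, "\n")
  if (nrow(x$log)) {
    last <- x$log[nrow(x$log), ]
    cat(sprintf("  %d epochs, val recons %.5f\n", last$epoch, last$val_recons))
  }
  invisible(x)
}

#' Encode an image to its latent grid
#'
#' @param model An `lh_vqvae`.
#' @param image Array matching the model's input shape.
#' @return List of class `lh_latent` with `encodings` (array
#'   `c(grid, n_z)`), `indices` (integer grid in `1..K`) and `quantized`.
#' @export
encode <- function(model, image) {
  stopifnot(inherits(model, "lh_vqvae"))
  if (!all(img_dim(image) == model$config$input_shape)) {
    stop("image shape ", paste(img_dim(image), collapse = "x"),
         " does not match model input shape ",
         paste(model$config$input_shape, collapse = "x"))
  }
  P <- image_to_patches(image, model$config$f)
  enc <- encoder_forward(model$params, P)
  q <- quantize(enc$Z, model$codebook)
  g <- latent_shape(model$config)
  structure(list(
    encodings = array(enc$Z, c(g, model$config$n_z)),
    indices = array(q$indices, g),
    quantized = array(q$quantized, c(g, model$config$n_z))
  ), class = "lh_latent")
}

#' Decode latent indices (or quantized vectors) back to an image
#'
#' @param model An `lh_vqvae`.
#' @param indices Integer grid (or vector) of codebook indices in `1..K`;
#'   alternatively pass `quantized` directly.
#' @param quantized Optional matrix/array of quantized vectors.
#' @return Image array of the model's input shape, values in (0,1).
#' @export
decode <- function(model, indices = NULL, quantized = NULL) {
  stopifnot(inherits(model, "lh_vqvae"))
  cfg <- model$config
  if (is.null(quantized)) {
    idx <- as.integer(indices)
    if (any(idx < 1L | idx > cfg$K)) {
      stop("latent indices must lie in 1..K = 1..", cfg$K)
    }
    Q <- model$codebook$vectors[idx, , drop = FALSE]
  } else {
    Q <- matrix(quantized, ncol = cfg$n_z)
  }
  dec <- decoder_forward(model$params, Q)
  patches_to_image(dec$Xhat, cfg$input_shape, cfg$f)
}

#' Plain VQ-VAE reconstruction of an image
#'
#' @param model An `lh_vqvae`.
#' @param image Input image.
#' @return Reconstructed image.
#' @export
reconstruct <- function(model, image) {
  lat <- encode(model, image)
  decode(model, indices = lat$indices)
}
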