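test_that("quantize matches exact codebook rows and breaks ties low", {
  E <- matrix(c(0, 0, 1, 1, 2, 2, 5, 5), 4, 2, byrow = TRUE)
  q <- quantize(matrix(c(1, 1), 1), E)
  expect_equal(q$indices, 2L)
  expect_equal(as.vector(q$quantized), c(1, 1))
  ## equidistant between rows 2 (1,1) and 3 (2,2): lowest index wins
  tie <- quantize(matrix(c(1.5, 1.5), 1), E)
  expect_equal(tie$indices, 2L)
})

test_that("quantize agrees with an exhaustive nearest-neighbour scan", {
  with_seed(42, {
    for (rep in 1:20) {
      K <- sample(2:9, 1)
      nz <- sample(2:6, 1)
      Z <- matrix(rnorm(5 * nz), 5)
      E <- matrix(rnorm(K * nz), K)
      got <- quantize(Z, E)$indices
      want <- apply(Z, 1, function(z) {
        which.min(colSums((t(E) - z)^2))
      })
      expect_equal(got, unname(want))
    }
  })
})

test_that("quantize rejects non-finite encodings", {
  expect_error(quantize(matrix(c(NA, 1), 1), matrix(0, 2, 2)), "non-finite")
})

test_that("encode obeys the latent shape contract and determinism", {
  s <- tiny_setup()
  lat <- encode(s$vqvae, s$images[[1]])
  expect_equal(dim(lat$indices), c(4, 4))
  expect_equal(dim(lat$encodings), c(4, 4, 64))
  lat2 <- encode(s$vqvae, s$images[[1]])
  expect_identical(lat$encodings, lat2$encodings)
  expect_error(encode(s$vqvae, array(0, c(16, 16))), "32x32")
})

test_that("decode round-trips shape, validates indices, and is deterministic", {
  s <- tiny_setup()
  lat <- encode(s$vqvae, s$images[[2]])
  img <- decode(s$vqvae, indices = lat$indices)
  expect_equal(dim(img), c(32, 32))
  expect_true(all(img >= 0 & img <= 1))
  expect_identical(img, decode(s$vqvae, indices = lat$indices))
  expect_error(decode(s$vqvae, indices = array(99L, c(4, 4))), "1..K")
})

test_that("loss terms follow the mean-reduction definitions", {
  x <- array(0.5, c(8, 8))
  z <- matrix(0.3, 4, 2)
  l0 <- vqvae_loss(x, x, z, z)
  expect_equal(l0$total, 0)
  ## two pixels differing by 0.5 under the per-pixel mean convention
  xh <- x
  xh[1] <- x[1] + 0.5
  xh[2] <- x[2] - 0.5
  l1 <- vqvae_loss(x, xh, z, z, beta = 0.25)
  expect_equal(l1$recons, 2 * 0.25 / 64)
  ## doubling beta adds exactly one extra commit share
  q <- z + 0.1
  la <- vqvae_loss(x, xh, z, q, beta = 0.25)
  lb <- vqvae_loss(x, xh, z, q, beta = 0.5)
  expect_equal(lb$total - la$total, 0.25 * la$commit)
  ## without EMA the codebook term reappears
  lc <- vqvae_loss(x, xh, z, q, beta = 0.25, ema = FALSE)
  expect_equal(lc$codebook_term, lc$commit)
  expect_equal(la$codebook_term, 0)
})

test_that("EMA update matches the hand-computed recurrence", {
  nz <- 2
  cb <- latentheal:::new_codebook(2, nz, decay = 0.99, epsilon = 1e-5,
                                  init = matrix(0, 2, nz))
  cb$vectors <- matrix(c(1, 1, 5, 5), 2, byrow = TRUE)
  cb$ema_cluster_size <- c(2, 3)
  cb$ema_embedding_sum <- matrix(c(2, 2, 15, 15), 2, byrow = TRUE)
  enc <- matrix(c(0, 0, 2, 2, 6, 6), 3, byrow = TRUE)
  idx <- c(1L, 1L, 2L)
  up <- ema_update(cb, enc, idx)
  ## hand recurrence, decay = 0.99
  size_exp <- 0.99 * c(2, 3) + 0.01 * c(2, 1)
  sum_exp <- 0.99 * matrix(c(2, 2, 15, 15), 2, byrow = TRUE) +
    0.01 * matrix(c(2, 2, 6, 6), 2, byrow = TRUE)
  expect_equal(up$ema_cluster_size, size_exp)
  expect_equal(up$ema_embedding_sum, sum_exp)
  n <- sum(size_exp)
  smoothed <- (size_exp + 1e-5) / (n + 2 * 1e-5) * n
  expect_equal(up$vectors, sum_exp / smoothed)
})

test_that("decay-zero EMA sets a fully-assigned code to the batch mean", {
  nz <- 3
  cb <- latentheal:::new_codebook(2, nz, decay = 0, epsilon = 1e-8,
                                  init = matrix(0.5, 2, nz))
  enc <- matrix(rnorm(12), 4)
  up <- ema_update(cb, enc, rep(1L, 4))
  expect_equal(up$vectors[1, ], colMeans(enc), tolerance = 1e-5)
})

test_that("a never-assigned code drifts only by Laplace smoothing", {
  nz <- 2
  cb <- latentheal:::new_codebook(3, nz, decay = 0.99, epsilon = 1e-5,
                                  init = matrix(0, 3, nz))
  cb$vectors <- matrix(1:6 / 2, 3, 2)
  cb$ema_cluster_size <- rep(4, 3)
  cb$ema_embedding_sum <- cb$vectors * 4
  enc <- matrix(rnorm(4), 2)
  up <- ema_update(cb, enc, c(1L, 1L))
  expect_equal(up$vectors[3, ], cb$vectors[3, ], tolerance = 1e-4)
})

test_that("straight-through gradients treat quantization as identity", {
  ## with beta = 0 the encoding gradient must equal the finite-difference
  ## gradient of the reconstruction loss w.r.t. the *quantized* input
  ## With beta = 0, dL/d encodings = dL/d quantized. On a one-row batch the
  ## encoder bias gradient db2 equals dL/dZ, so comparing db2 against the
  ## finite-difference gradient of the loss w.r.t. the quantized vector
  ## checks the straight-through identity through the whole backward pass.
  with_seed(3, {
    p <- 4
    params <- latentheal:::init_params(p, 8, p)
    params$W2 <- matrix(rnorm(8 * p, sd = 0.1), 8, p)  # active warp
    cb <- latentheal:::new_codebook(3, p, init = matrix(runif(3 * p), 3, p))
    P <- matrix(runif(p), 1)
    g <- latentheal:::vqvae_gradients(params, P, cb, beta = 0)
    enc <- latentheal:::encoder_forward(params, P)
    q <- quantize(enc$Z, cb)
    loss_at <- function(Q) {
      dec <- latentheal:::decoder_forward(params, Q)
      mean((P - dec$Xhat)^2)
    }
    h <- 1e-6
    for (j in seq_len(p)) {
      Qp <- q$quantized; Qp[1, j] <- Qp[1, j] + h
      Qm <- q$quantized; Qm[1, j] <- Qm[1, j] - h
      num <- (loss_at(Qp) - loss_at(Qm)) / (2 * h)
      expect_equal(g$grads$b2[j], num, tolerance = 1e-5)
    }
  })
})

test_that("latent indices shift with exact f-pixel image translations", {
  s <- tiny_setup()
  img <- s$images[[3]]
  shifted <- rbind(matrix(0, 8, 32), img[1:24, ])  # shift down by f = 8
  a <- encode(s$vqvae, img)$indices
  b <- encode(s$vqvae, shifted)$indices
  expect_equal(b[2:4, ], a[1:3, ])
})

test_that("training reduces reconstruction loss deterministically", {
  s <- tiny_setup()
  log <- s$vqvae$log
  expect_lt(log$train_recons[nrow(log)], log$train_recons[1])
  expect_false(any(is.na(log$val_recons)))
  ## reproducibility: a second run with the same seed gives the same log
  cfg <- vqvae_config(c(32, 32), f = 8, K = 16, hidden = 64, epochs = 2,
                      batch_size = 16, seed = 5)
  m1 <- train_vqvae(s$images[1:30], cfg)
  m2 <- train_vqvae(s$images[1:30], cfg)
  expect_identical(m1$log, m2$log)
  expect_identical(m1$codebook$vectors, m2$codebook$vectors)
})

test_that("several codebook entries stay active on varied phantoms", {
  s <- tiny_setup()
  idx <- unlist(lapply(s$images[1:20],
                       function(x) as.vector(encode(s$vqvae, x)$indices)))
  expect_gt(length(unique(idx)), 1)
})

test_that("training on constant images drives reconstruction error to zero", {
  imgs <- lapply(1:24, function(i) array(0, c(16, 16)))
  cfg <- vqvae_config(c(16, 16), f = 8, K = 4, hidden = 32, epochs = 40,
                      batch_size = 8, lr = 5e-2, seed = 2)
  m <- train_vqvae(imgs, cfg)
  rec <- reconstruct(m, imgs[[1]])
  expect_lt(mean((rec - imgs[[1]])^2), 1e-3)
})

test_that("3D images encode and decode through the same machinery", {
  imgs <- lapply(1:12, function(i) generate_phantom(i, c(16, 16, 16))$image)
  cfg <- vqvae_config(c(16, 16, 16), f = 4, K = 8, hidden = 32, epochs = 3,
                      batch_size = 6, seed = 3)
  m <- train_vqvae(imgs, cfg)
  lat <- encode(m, imgs[[1]])
  expect_equal(dim(lat$indices), c(4, 4, 4))
  rec <- decode(m, indices = lat$indices)
  expect_equal(dim(rec), c(16, 16, 16))
})

test_that("image shape mismatches abort training with a clear error", {
  cfg <- vqvae_config(c(32, 32), f = 8, K = 8, epochs = 1, seed = 1)
  expect_error(train_vqvae(list(array(0, c(16, 16)), array(0, c(16, 16))),
                           cfg),
               "does not match")
})
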