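test_that("the resampling mask applies the <= threshold rule exactly", {
  m <- resampling_mask(c(0.5, 0.004, 0.9), threshold = 0.005)
  expect_equal(m$m, c(0L, 1L, 0L))
  ## ties count as anomalous
  expect_equal(resampling_mask(c(0.005, 0.0051), 0.005)$m, c(1L, 0L))
  ## the illustrative 0.05 regime marks everything at or below 0.05
  p <- c(0.2, 0.05, 0.04, 0.9, 0.051)
  expect_equal(resampling_mask(p, 0.05)$m, c(0L, 1L, 1L, 0L, 0L))
  ## limits
  expect_equal(resampling_mask(p, 1e-12)$m, rep(0L, 5))
  expect_equal(resampling_mask(p, 1 - 1e-12)$m, rep(1L, 5))
  expect_error(resampling_mask(p, 0))
  expect_error(resampling_mask(p, 1.5))
})

test_that("healing with an all-zero mask is the identity", {
  s <- tiny_setup()
  dm <- s$members[[1]]$density
  tok <- image_tokens(s$vqvae, s$images[[1]], s$members[[1]]$ordering)
  healed <- heal_sequence(dm, tok, rep(0L, length(tok)), rng_seed = 1)
  expect_identical(healed, as.integer(tok))
})

test_that("a near-one-hot model heals to its preferred sequence", {
  d <- 10; K <- 6
  pref <- as.integer((seq_len(d) %% K) + 1L)
  m <- toy_onehot_density(d, K, pref)
  healed <- heal_sequence(m, rep(1L, d), rep(1L, d), rng_seed = 3)
  expect_identical(healed, pref)
})

test_that("only masked positions change, and draws follow the seed", {
  m <- density_model(K = 16, d = 12)  # uniform sampler
  tok <- rep(5L, 12)
  mask <- as.integer(seq_len(12) %% 2 == 0)
  h1 <- heal_sequence(m, tok, mask, rng_seed = 1)
  h2 <- heal_sequence(m, tok, mask, rng_seed = 1)
  h3 <- heal_sequence(m, tok, mask, rng_seed = 2)
  expect_identical(h1, h2)
  expect_identical(h1[mask == 0L], tok[mask == 0L])
  expect_identical(h3[mask == 0L], tok[mask == 0L])
  expect_false(identical(h1[mask == 1L], h3[mask == 1L]))
})

test_that("residual maps follow the absolute and positive-part definitions", {
  x <- matrix(c(0.2, 0.9), 1)
  xh <- matrix(c(0.5, 0.4), 1)
  expect_equal(as.vector(residual_map(x, xh)), c(0.3, 0.5))
  expect_equal(as.vector(residual_map(x, xh, signed = TRUE)), c(0, 0.5))
  with_seed(4, {
    a <- matrix(runif(64), 8)
    b <- matrix(runif(64), 8)
    expect_true(all(residual_map(a, b, signed = TRUE) <= residual_map(a, b)))
    expect_equal(residual_map(a, a), matrix(0, 8, 8))
  })
})

test_that("latent mask upsampling handles the constant limits exactly", {
  o <- raster_ordering(c(4, 4))
  ones <- latent_mask_to_image_mask(rep(1L, 16), o, c(32, 32), sigma = 2)
  expect_equal(ones, array(1, c(32, 32)))
  zeros <- latent_mask_to_image_mask(rep(0L, 16), o, c(32, 32), sigma = 2)
  expect_equal(zeros, array(0, c(32, 32)))
})

test_that("a single active latent cell yields a centred unimodal bump", {
  o <- raster_ordering(c(4, 4))
  m <- rep(0L, 16)
  grid <- array(0L, c(4, 4)); grid[2, 3] <- 1L
  m <- apply_ordering(grid, o)
  img <- latent_mask_to_image_mask(m, o, c(32, 32), sigma = 2)
  peak <- which(img == max(img), arr.ind = TRUE)
  ## the cell (2,3) covers image rows 9-16, cols 17-24; even-sized patches
  ## peak on the 2x2 central pixels
  expect_true(all(peak[, 1] %in% 12:13))
  expect_true(all(peak[, 2] %in% 20:21))
  ## decays away from the patch
  expect_lt(img[1, 1], 0.01)
  expect_gt(max(img), 0.5)
})

test_that("masked residuals never exceed the unmasked residuals", {
  with_seed(5, {
    r <- matrix(runif(64), 8)
    w <- matrix(runif(64), 8)
    mr <- masked_residual(r, w)
    expect_true(all(mr <= r))
    expect_equal(masked_residual(r, matrix(1, 8, 8)), r)
    expect_equal(masked_residual(r, matrix(0, 8, 8)), matrix(0, 8, 8))
  })
})

test_that("binarize thresholds strictly above", {
  expect_equal(as.vector(binarize(matrix(c(0.1, 0.6), 1), 0.5)), c(0L, 1L))
  r <- matrix(c(0, 0.2, 0.5), 1)
  expect_equal(as.vector(binarize(r, 0)), c(0L, 1L, 1L))
  expect_equal(as.vector(binarize(r, 0.9)), c(0L, 0L, 0L))
})

test_that("an empty resampling mask reproduces the plain reconstruction", {
  s <- tiny_setup()
  mem <- s$members[[1]]
  img <- s$images[[7]]
  tok <- image_tokens(s$vqvae, img, mem$ordering)
  prof <- sequence_likelihood(mem$density, tok, mem$ordering)
  thr <- min(prof$p) / 2  # below every observed likelihood: mask is empty
  seg <- segment_single(img, s$vqvae, mem$density, mem$ordering,
                        threshold = thr, rng_seed = 1)
  expect_equal(sum(seg$resampling_mask$m), 0)
  expect_identical(seg$healed_tokens, as.integer(tok))
  expect_identical(seg$healed_image, reconstruct(s$vqvae, img))
  ## and the all-zero mask filters the residual to exactly zero
  expect_equal(seg$residual, array(0, dim(img)))
})

test_that("segmentation of a normal image flags few tokens", {
  s <- tiny_setup()
  mem <- s$members[[1]]
  seg <- segment_single(s$images[[9]], s$vqvae, mem$density, mem$ordering,
                        threshold = 0.005, rng_seed = 2)
  expect_lte(sum(seg$resampling_mask$m), 3)
})

test_that("masked tokens concentrate on sprite-covered latent cells", {
  s <- tiny_setup()
  mem <- s$members[[1]]
  ph <- generate_phantom(777, s$size)
  spr <- generate_sprite(778, s$size, "square")
  cs <- contaminate(ph, spr, intensity = 1, rng_seed = 779)
  seg <- segment_single(cs$image, s$vqvae, mem$density, mem$ordering,
                        threshold = 0.005, rng_seed = 3)
  mgrid <- invert_ordering(seg$resampling_mask$m, mem$ordering)
  gt_lat <- latentheal:::downsample_mean(cs$gt_mask, 8) > 0
  expect_gt(sum(mgrid[gt_lat]), 0)
  expect_gte(mean(mgrid[gt_lat]), mean(mgrid[!gt_lat]))
})

test_that("segmentation is reproducible under a fixed seed", {
  s <- tiny_setup()
  mem <- s$members[[1]]
  a <- segment_single(s$images[[11]], s$vqvae, mem$density, mem$ordering,
                      rng_seed = 5)
  b <- segment_single(s$images[[11]], s$vqvae, mem$density, mem$ordering,
                      rng_seed = 5)
  expect_identical(a$residual, b$residual)
})

test_that("a one-member ensemble equals the single-model path", {
  s <- tiny_setup()
  mem <- s$members[[1]]
  ens <- segment_ensemble(s$images[[2]], s$vqvae, list(mem), rng_seed = 8)
  single <- segment_single(s$images[[2]], s$vqvae, mem$density, mem$ordering,
                           rng_seed = latentheal:::derive_seed(8, 1))
  expect_identical(ens$residual, single$residual)
})

test_that("the ensemble mean residual is bounded by the member maps", {
  s <- tiny_setup()
  ens <- segment_ensemble(s$images[[4]], s$vqvae, s$members, rng_seed = 9,
                          keep_members = TRUE)
  stack <- vapply(ens$members, `[[`, array(0, dim(s$images[[4]])), "residual")
  expect_true(all(ens$residual <= apply(stack, c(1, 2), max) + 1e-12))
  expect_true(all(ens$residual >= apply(stack, c(1, 2), min) - 1e-12))
})

test_that("the healing chain also runs end to end in 3D", {
  imgs <- lapply(1:14, function(i) generate_phantom(i, c(16, 16, 16))$image)
  cfg <- vqvae_config(c(16, 16, 16), f = 4, K = 8, hidden = 32, epochs = 3,
                      batch_size = 6, seed = 3)
  vq <- train_vqvae(imgs, cfg)
  o <- ensemble_orderings("raster", c(4, 4, 4), 2)
  seqs <- lapply(imgs, image_tokens, vqvae = vq, ordering = o[[1]])
  dm <- train_density_model(seqs, K = 8, ordering = o[[1]], seed = 4)
  seg <- segment_single(imgs[[1]], vq, dm, o[[1]], threshold = 0.001,
                        rng_seed = 1)
  expect_equal(dim(seg$residual), c(16, 16, 16))
  expect_true(all(seg$residual >= 0))
})
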