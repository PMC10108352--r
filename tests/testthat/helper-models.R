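## Shared fixtures, built in code and cached for the test run.

.fixture_cache <- new.env(parent = emptyenv())

cache_get <- function(name, builder) {
  if (is.null(.fixture_cache[[name]])) .fixture_cache[[name]] <- builder()
  .fixture_cache[[name]]
}

## Tiny 2D pipeline: 80 phantoms of 32x32, 4x4 latent grid, K = 16.
tiny_setup <- function() {
  cache_get("tiny", function() {
    size <- c(32L, 32L)
    imgs <- lapply(1:80, function(i) generate_phantom(100 + i, size)$image)
    cfg <- vqvae_config(size, f = 8, K = 16, hidden = 64, epochs = 8,
                        batch_size = 16, seed = 7)
    vq <- train_vqvae(imgs, cfg)
    orderings <- ensemble_orderings("raster", c(4L, 4L), 4)
    members <- lapply(seq_along(orderings), function(i) {
      seqs <- lapply(imgs, image_tokens, vqvae = vq,
                     ordering = orderings[[i]])
      list(density = train_density_model(seqs, K = 16,
                                         ordering = orderings[[i]],
                                         seed = 30 + i),
           ordering = orderings[[i]])
    })
    list(size = size, images = imgs, vqvae = vq, orderings = orderings,
         members = members)
  })
}

## Density model that (almost surely) prefers one fixed token per position:
## positional counts overwhelm the smoothing.
toy_onehot_density <- function(d, K, preferred) {
  stopifnot(length(preferred) == d)
  m <- density_model(K, d, context_order = 0)
  m$pos_counts[cbind(seq_len(d), preferred)] <- 1e9
  m$glob_counts <- rep(1, K)
  m
}

## Random binary grid helper for ordering round trips.
random_grid <- function(shape, seed) {
  with_seed(seed, array(sample.int(9, prod(shape), replace = TRUE), shape))
}

with_seed <- latentheal:::with_seed
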