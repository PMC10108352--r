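## Autoregressive density model over latent token sequences.
##
## One model per ordering. The model is a back-off categorical estimator
## whose context at sequence position i is the tokens of the grid cells
## adjacent to cell i that were already visited earlier in the ordering
## (for a raster ordering: the cells to the left and above). This makes the
## role of the ordering explicit -- different orderings expose different
## neighbourhoods as context -- while keeping the model strictly causal:
## every context position precedes i in the sequence. The next-token
## distribution interpolates, by recursive Dirichlet smoothing, between the
## (position, context) counts at decreasing context depths, the positional
## counts, the global token counts and the uniform distribution. An
## untrained model is exactly uniform, every distribution sums to one by
## construction, and training maximizes the training sequences'
## log-likelihood (minimizes the mean sequence negative log-likelihood) in
## closed form by counting.

BOS <- 0L

## Sequence positions used as context for each position i: the up-to-`order`
## most recently visited grid neighbours of cell i under `ordering`, or the
## plain sequence lags 1..order when no ordering is given. 0 marks "before
## the sequence" (begin-of-sequence).
context_positions <- function(d, order, ordering = NULL) {
  ctx <- matrix(0L, d, max(order, 1L))
  if (order == 0L) return(ctx[, 0, drop = FALSE])
  if (is.null(ordering)) {
    for (l in seq_len(order)) ctx[, l] <- pmax(seq_len(d) - l, 0L)
    return(ctx)
  }
  shape <- ordering$shape
  nd <- length(shape)
  offsets <- rbind(diag(nd), -diag(nd))
  coords <- arrayInd(ordering$perm, shape)
  strides <- cumprod(c(1L, shape[-nd]))
  for (t in seq_len(d)) {
    pc <- coords[t, ]
    earlier <- integer(0)
    for (o in seq_len(nrow(offsets))) {
      q <- pc + offsets[o, ]
      if (any(q < 1L) || any(q > shape)) next
      lin <- as.integer(1 + sum((q - 1) * strides))
      tq <- ordering$inv[lin]
      if (tq < t) earlier <- c(earlier, tq)
    }
    earlier <- sort(earlier, decreasing = TRUE)  # most recent first
    n <- min(length(earlier), order)
    if (n > 0L) ctx[t, seq_len(n)] <- earlier[seq_len(n)]
  }
  ctx
}

#' Create an (untrained) latent sequence density model
#'
#' @param K Vocabulary size (codebook size); tokens are integers in `1..K`,
#'   missing/begin-of-sequence context is token `0`.
#' @param d Sequence length (number of latent grid cells).
#' @param context_order Maximum number of context tokens per position. With
#'   an `ordering`, contexts are the most recently visited grid neighbours
#'   of each cell; without one, the preceding `context_order` sequence
#'   positions.
#' @param alpha Dirichlet back-off strength at every level.
#' @param ordering Optional `lh_ordering` descriptor the model is bound to;
#'   it shapes the context structure, and scoring refuses sequences produced
#'   under a different ordering.
#' @return An object of class `lh_density`.
#' @export
density_model <- function(K, d, context_order = 2, alpha = 1,
                          ordering = NULL) {
  stopifnot(K >= 2, d >= 1, context_order >= 0, alpha > 0)
  context_order <- as.integer(context_order)
  levels <- lapply(seq_len(context_order),
                   function(l) new.env(parent = emptyenv()))
  structure(list(
    K = as.integer(K), d = as.integer(d),
    context_order = context_order, alpha = alpha,
    ordering_name = if (is.null(ordering)) NULL else ordering$name,
    ctx_pos = context_positions(d, context_order, ordering),
    levels = levels,
    pos_counts = matrix(0, d, K),
    glob_counts = rep(0, K),
    n_sequences = 0L,
    log = NULL
  ), class = "lh_density")
}

#' @export
print.lh_density <- function(x, ...) {
  cat("<lh_density> K =", x$K, "d =", x$d, "order =", x$context_order,
      "trained on", x$n_sequences, "sequences\n")
  invisible(x)
}

check_sequence <- function(model, tokens) {
  if (length(tokens) != model$d) {
    stop("sequence length ", length(tokens),
         " does not match the model's trained context length ", model$d)
  }
  if (any(tokens < 1L | tokens > model$K)) {
    stop("tokens must lie in 1..K = 1..", model$K)
  }
  invisible(TRUE)
}

check_ordering_match <- function(model, ordering) {
  if (!is.null(model$ordering_name) && !is.null(ordering) &&
      !identical(model$ordering_name, ordering$name)) {
    stop("sequence ordering '", ordering$name,
         "' does not match the ordering this model was trained under ('",
         model$ordering_name, "')")
  }
  invisible(TRUE)
}

## context tokens for position i, given (possibly partially healed) tokens
context_at <- function(model, tokens, i) {
  if (model$context_order == 0L) return(integer(0))
  pos <- model$ctx_pos[i, ]
  ifelse(pos > 0L, tokens[pmax(pos, 1L)], BOS)
}

level_key <- function(i, ctx, l) {
  paste(i, paste(ctx[seq_len(l)], collapse = ","), sep = "|")
}

## Back-off distribution for position i under context ctx (vector of length
## context_order). Deeper levels refine shallower ones; an unseen context at
## level l implies all deeper contexts are unseen too.
backoff_distribution <- function(model, i, ctx) {
  K <- model$K
  a <- model$alpha
  p <- rep(1 / K, K)
  gt <- sum(model$glob_counts)
  p <- (model$glob_counts + a * p) / (gt + a)
  pt <- sum(model$pos_counts[i, ])
  p <- (model$pos_counts[i, ] + a * p) / (pt + a)
  if (model$context_order > 0L) {
    for (l in seq_len(model$context_order)) {
      cc <- model$levels[[l]][[level_key(i, ctx, l)]]
      if (is.null(cc)) break
      p <- (cc$counts + a * p) / (cc$total + a)
    }
  }
  p
}

#' Per-position next-token distributions (teacher-forced)
#'
#' Row `i` is the model's categorical distribution over the K tokens at
#' position `i` given the observed tokens at its context positions (all of
#' which precede `i` in the sequence). Each row sums to one.
#'
#' @param model An `lh_density`.
#' @param tokens Integer sequence of length `d`, values in `1..K`.
#' @param ordering Optional `lh_ordering` the sequence was produced under;
#'   checked against the model's bound ordering.
#' @return A `d x K` matrix of probabilities.
#' @export
next_token_distributions <- function(model, tokens, ordering = NULL) {
  stopifnot(inherits(model, "lh_density"))
  check_sequence(model, tokens)
  check_ordering_match(model, ordering)
  out <- matrix(0, model$d, model$K)
  for (i in seq_len(model$d)) {
    out[i, ] <- backoff_distribution(model, i, context_at(model, tokens, i))
  }
  out
}

#' Likelihood profile of a token sequence
#'
#' @inheritParams next_token_distributions
#' @return List of class `lh_likelihood` with `p` (probability the model
#'   assigns to each observed token) and `logp_total = sum(log(p))`.
#' @export
sequence_likelihood <- function(model, tokens, ordering = NULL) {
  dist <- next_token_distributions(model, tokens, ordering)
  p <- dist[cbind(seq_len(model$d), as.integer(tokens))]
  structure(list(p = p, logp_total = sum(log(p))), class = "lh_likelihood")
}

#' Sample a token from a categorical distribution
#'
#' Ancestral sampling with optional temperature (probabilities are raised to
#' `1/temperature` and renormalized). Uses the current RNG state; seed with
#' `set.seed()` or the healing functions' `rng_seed` arguments for
#' reproducibility.
#'
#' @param distribution Probability vector over the K tokens.
#' @param temperature Positive scalar, default 1 (plain sampling).
#' @return An integer token in `1..K`.
#' @export
sample_next <- function(distribution, temperature = 1) {
  stopifnot(temperature > 0, all(distribution >= 0))
  if (temperature != 1) {
    distribution <- distribution^(1 / temperature)
  }
  sample.int(length(distribution), 1L, prob = distribution)
}

#' Train the density model on token sequences from normal images
#'
#' All sequences must come from one fixed ordering (one model per ordering).
#' Fitting is exact maximum likelihood by counting; the training log records
#' the held-out mean negative log-likelihood before (uniform) and after
#' fitting.
#'
#' @param sequences List of integer token sequences (each length `d`, values
#'   in `1..K`).
#' @param K Vocabulary size.
#' @param ordering Optional `lh_ordering` descriptor bound to the model.
#' @param context_order,alpha Model hyperparameters, see [density_model()].
#' @param val_frac Held-out fraction for the log.
#' @param seed Seed for the held-out split.
#' @return A trained `lh_density` with a `log` tibble.
#' @export
train_density_model <- function(sequences, K, ordering = NULL,
                                context_order = 2, alpha = 1,
                                val_frac = 0.1, seed = 1) {
  stopifnot(length(sequences) >= 1L)
  d <- length(sequences[[1]])
  model <- density_model(K, d, context_order, alpha, ordering)
  n <- length(sequences)
  n_val <- if (n >= 10L) max(1L, round(val_frac * n)) else 0L
  ids <- with_seed(seed, sample.int(n))
  val_ids <- ids[seq_len(n_val)]
  train_ids <- setdiff(ids, val_ids)

  nll <- function(seqs) {
    if (!length(seqs)) return(NA_real_)
    -mean(vapply(seqs, function(s) sequence_likelihood(model, s)$logp_total,
                 0))
  }
  nll_init <- d * log(K)  # uniform model
  L <- model$context_order
  for (id in train_ids) {
    s <- as.integer(sequences[[id]])
    check_sequence(model, s)
    model$glob_counts <- model$glob_counts + tabulate(s, nbins = K)
    model$pos_counts[cbind(seq_len(d), s)] <-
      model$pos_counts[cbind(seq_len(d), s)] + 1
    if (L > 0L) {
      for (i in seq_len(d)) {
        ctx <- context_at(model, s, i)
        for (l in seq_len(L)) {
          key <- level_key(i, ctx, l)
          cc <- model$levels[[l]][[key]]
          if (is.null(cc)) cc <- list(counts = rep(0, K), total = 0)
          cc$counts[s[i]] <- cc$counts[s[i]] + 1
          cc$total <- cc$total + 1
          model$levels[[l]][[key]] <- cc
        }
      }
    }
  }
  model$n_sequences <- length(train_ids)
  heldout <- if (n_val > 0L) sequences[val_ids] else sequences[train_ids]
  model$log <- tibble::tibble(
    n_train = length(train_ids), n_val = n_val,
    nll_initial = nll_init, nll_heldout = nll(heldout))
  if (!is.finite(model$log$nll_heldout)) {
    stop("density model training produced a non-finite loss")
  }
  model
}

#' Tokens of an image under a model and ordering
#'
#' Convenience: encode, take the index grid, flatten under `ordering`.
#'
#' @param vqvae An `lh_vqvae`.
#' @param image Input image.
#' @param ordering An `lh_ordering` over the model's latent grid.
#' @return Integer token sequence.
#' @export
image_tokens <- function(vqvae, image, ordering) {
  lat <- encode(vqvae, image)
  apply_ordering(lat$indices, ordering)
}
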