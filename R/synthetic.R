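## Synthetic study data: head-like phantoms as stand-ins for normal training
## images, binary "sprite" shapes as synthetic anomalies, and far-OOD
## fixtures (uniform noise, multi-lobe shapes) for detection experiments.

ellipse_r2 <- function(size, center, axes, theta = 0) {
  if (length(size) == 2L) {
    ii <- matrix(seq_len(size[1]), size[1], size[2])
    jj <- matrix(seq_len(size[2]), size[1], size[2], byrow = TRUE)
    dx <- ii - center[1]
    dy <- jj - center[2]
    u <- dx * cos(theta) + dy * sin(theta)
    v <- -dx * sin(theta) + dy * cos(theta)
    (u / axes[1])^2 + (v / axes[2])^2
  } else {
    co <- lapply(seq_along(size), function(a) {
      sl <- slice.index(array(0, size), a)
      (sl - center[a]) / axes[a]
    })
    Reduce(`+`, lapply(co, function(z) z^2))
  }
}

## Smooth random texture field in roughly [-1,1], seeded by the caller's RNG.
texture_field <- function(size, n_waves = 3L) {
  acc <- array(0, size)
  for (w in seq_len(n_waves)) {
    freq <- stats::runif(length(size), 0.5, 2.5) / size
    phase <- stats::runif(1, 0, 2 * pi)
    arg <- array(0, size)
    for (a in seq_along(size)) {
      arg <- arg + 2 * pi * freq[a] * slice.index(array(0, size), a)
    }
    acc <- acc + stats::runif(1, 0.5, 1) * cos(arg + phase)
  }
  acc / n_waves
}

#' Generate a head-like phantom image
#'
#' Produces a deterministic, seed-varied phantom: a bright elliptical "skull"
#' ring around a mid-gray interior with low-frequency texture and dark
#' ventricle-like blobs, on an exactly-zero background. `class = "multi_lobe"`
#' instead produces a hand-like union of elongated lobes, used as a
#' structurally different far-out-of-distribution class.
#'
#' @param rng_seed Integer seed; the phantom is a pure function of it.
#' @param size Integer vector of length 2 (image) or 3 (volume); every
#'   dimension must be at least 16.
#' @param class `"head"` (default) or `"multi_lobe"`.
#' @return An object of class `lh_phantom`: list with `image` (values in
#'   \[0,1\]) and binary `tissue_mask` marking the head region.
#' @export
generate_phantom <- function(rng_seed, size = c(64, 64),
                             class = c("head", "multi_lobe")) {
  class <- match.arg(class)
  size <- as.integer(size)
  if (any(size < 16L)) {
    stop("phantom size must be at least 16 in every dimension, got ",
         paste(size, collapse = "x"))
  }
  with_seed(rng_seed, {
    if (class == "head") phantom_head(size) else phantom_multi_lobe(size)
  })
}

phantom_head <- function(size) {
  nd <- length(size)
  center <- size / 2 + stats::runif(nd, -0.05, 0.05) * size
  axes <- stats::runif(nd, 0.30, 0.42) * size
  theta <- if (nd == 2L) stats::runif(1, 0, pi) else 0
  r2 <- ellipse_r2(size, center, axes, theta)
  tissue <- r2 <= 1

  ring_frac <- stats::runif(1, 0.78, 0.88)   # inner edge of the skull ring
  skull <- tissue & (r2 > ring_frac)
  interior <- tissue & !skull

  img <- array(0, size)
  base <- stats::runif(1, 0.35, 0.55)
  tex <- texture_field(size)
  img[interior] <- clip01(base + 0.08 * tex[interior])
  img[skull] <- stats::runif(1, 0.85, 1.0)

  ## ventricle-like dark blobs near the centre
  n_vent <- sample(1:3, 1)
  for (v in seq_len(n_vent)) {
    vcen <- center + stats::runif(nd, -0.12, 0.12) * size
    vax <- stats::runif(nd, 0.04, 0.10) * size
    vr2 <- ellipse_r2(size, vcen, vax, if (nd == 2L) stats::runif(1, 0, pi) else 0)
    dark <- (vr2 <= 1) & interior
    img[dark] <- stats::runif(1, 0.02, 0.12)
  }
  structure(list(image = img, tissue_mask = tissue * 1L), class = "lh_phantom")
}

phantom_multi_lobe <- function(size) {
  nd <- length(size)
  center <- size / 2 + stats::runif(nd, -0.05, 0.05) * size
  tissue <- array(FALSE, size)
  n_lobes <- sample(4:6, 1)
  img <- array(0, size)
  for (l in seq_len(n_lobes)) {
    ang <- stats::runif(1, 0, 2 * pi)
    off <- stats::runif(1, 0.10, 0.25) * min(size)
    lcen <- center + off * c(cos(ang), sin(ang), rep(0, nd - 2L))[seq_len(nd)]
    lax <- stats::runif(nd, 0.06, 0.22) * size
    lr2 <- ellipse_r2(size, lcen, lax, if (nd == 2L) ang else 0)
    lobe <- lr2 <= 1
    img[lobe] <- stats::runif(1, 0.55, 0.9)
    tissue <- tissue | lobe
  }
  structure(list(image = clip01(img), tissue_mask = tissue * 1L),
            class = "lh_phantom")
}

#' Generate a binary sprite (synthetic anomaly shape)
#'
#' The sprite is a single connected binary shape whose area falls inside
#' `area_range` (as a fraction of the grid). `"blob"` shapes are grown by
#' seeded random region growth, which guarantees connectivity and exact area.
#'
#' @param rng_seed Integer seed.
#' @param size Grid shape (length 2 or 3).
#' @param shape_class `"ellipse"`, `"square"` (axis-aligned filled
#'   rectangle) or `"blob"`.
#' @param area_range Length-2 numeric, admissible area fraction
#'   (default 2--15% of the grid).
#' @return Binary integer array of shape `size`.
#' @export
generate_sprite <- function(rng_seed, size = c(64, 64),
                            shape_class = c("ellipse", "square", "blob"),
                            area_range = c(0.02, 0.15)) {
  shape_class <- match.arg(shape_class)
  size <- as.integer(size)
  with_seed(rng_seed, {
    frac <- stats::runif(1, area_range[1], area_range[2])
    target <- max(1L, round(frac * prod(size)))
    nd <- length(size)
    center <- size * stats::runif(nd, 0.25, 0.75)
    m <- switch(shape_class,
      ellipse = {
        aspect <- stats::runif(1, 0.5, 2)
        if (nd == 2L) {
          a <- sqrt(target / pi * aspect)
          axes <- c(a, target / (pi * a))
        } else {
          r <- (target / (4 / 3 * pi))^(1 / 3)
          axes <- c(r * aspect, r, r / aspect)
        }
        theta <- if (nd == 2L) stats::runif(1, 0, pi) else 0
        (ellipse_r2(size, center, pmax(axes, 1), theta) <= 1) * 1L
      },
      square = {
        aspect <- stats::runif(1, 0.5, 2)
        if (nd == 2L) {
          h <- max(1, sqrt(target * aspect))
          w <- max(1, target / h)
          ext <- c(h, w)
        } else {
          e <- target^(1 / 3)
          ext <- pmax(1, c(e * aspect, e, e / aspect))
        }
        lo <- pmax(1L, round(center - ext / 2))
        hi <- pmin(size, lo + pmax(1L, round(ext)) - 1L)
        m <- array(0L, size)
        idx <- lapply(seq_len(nd), function(a) lo[a]:hi[a])
        m <- do.call(`[<-`, c(list(m), idx, list(value = 1L)))
        m
      },
      blob = grow_blob(size, center, target)
    )
    ## keep only the largest connected component (ellipse/square already are)
    lab <- label_components(m)
    if (max(lab) > 1L) {
      keep <- which.max(tabulate(lab[lab > 0]))
      m <- (lab == keep) * 1L
    }
    storage.mode(m) <- "integer"
    m
  })
}

## Random region growth: start from a seed cell and repeatedly annex a random
## frontier neighbour until the target area is reached.
grow_blob <- function(size, center, target) {
  nd <- length(size)
  m <- array(0L, size)
  strides <- cumprod(c(1L, size[-nd]))
  start <- pmin(pmax(round(center), 1L), size)
  start_lin <- as.integer(1 + sum((start - 1) * strides))
  m[start_lin] <- 1L
  offsets <- rbind(diag(nd), -diag(nd))
  frontier <- start_lin
  n <- 1L
  while (n < target && length(frontier)) {
    pick <- frontier[sample.int(length(frontier), 1L)]
    pc <- arrayInd(pick, size)[1, ]
    nb <- integer(0)
    for (o in seq_len(nrow(offsets))) {
      q <- pc + offsets[o, ]
      if (any(q < 1L) || any(q > size)) next
      ql <- as.integer(1 + sum((q - 1) * strides))
      if (m[ql] == 0L) nb <- c(nb, ql)
    }
    if (!length(nb)) {
      frontier <- setdiff(frontier, pick)
      next
    }
    new <- nb[sample.int(length(nb), 1L)]
    m[new] <- 1L
    n <- n + 1L
    frontier <- union(frontier, new)
    if (length(nb) == 1L) frontier <- setdiff(frontier, pick)
  }
  m
}

#' Composite a sprite anomaly onto a phantom
#'
#' Pixels under the sprite support are set to `intensity` (plus optional
#' additive Gaussian noise of standard deviation `noise_sd`), then the image
#' is clipped to \[0,1\]. The sprite must overlap the phantom's tissue mask by
#' at least `min_overlap` of its area; otherwise it is randomly repositioned
#' up to `max_retries` times before failing.
#'
#' @param phantom An `lh_phantom`.
#' @param sprite Binary array of the same shape as `phantom$image`.
#' @param intensity Scalar in \[0,1\], the anomaly's intensity value.
#' @param noise_sd Non-negative scalar; Gaussian noise added on sprite pixels.
#' @param rng_seed Integer seed (noise and repositioning).
#' @param min_overlap Minimum fraction of the sprite over tissue.
#' @param max_retries Repositioning attempts before giving up.
#' @return An object of class `lh_contaminated`: list with `image`,
#'   binary `gt_mask` (the composited sprite support), `sprite_intensity`,
#'   `noise_sd`.
#' @export
contaminate <- function(phantom, sprite, intensity, noise_sd = 0,
                        rng_seed = 0, min_overlap = 0.5, max_retries = 20) {
  stopifnot(inherits(phantom, "lh_phantom"),
            intensity >= 0, intensity <= 1, noise_sd >= 0)
  size <- img_dim(phantom$image)
  stopifnot(all(img_dim(sprite) == size))
  with_seed(rng_seed, {
    area <- sum(sprite > 0)
    if (area > 0) {
      overlap <- function(s) sum(s > 0 & phantom$tissue_mask > 0) / area
      tissue_cells <- which(phantom$tissue_mask > 0)
      tries <- 0L
      base_sprite <- sprite
      while (overlap(sprite) < min_overlap) {
        tries <- tries + 1L
        if (tries > max_retries || !length(tissue_cells)) {
          stop("could not place sprite with tissue overlap >= ", min_overlap,
               " after ", max_retries, " retries")
        }
        ## recentre the sprite on a randomly chosen tissue cell
        target <- arrayInd(tissue_cells[sample.int(length(tissue_cells), 1L)],
                           size)[1, ]
        centroid <- round(colMeans(which(base_sprite > 0, arr.ind = TRUE)))
        sprite <- translate_mask(base_sprite, target - centroid)
      }
    }
    img <- phantom$image
    sel <- sprite > 0
    img[sel] <- intensity
    if (noise_sd > 0 && any(sel)) {
      img[sel] <- img[sel] + stats::rnorm(sum(sel), 0, noise_sd)
    }
    structure(list(image = clip01(img), gt_mask = (sprite > 0) * 1L,
                   sprite_intensity = intensity, noise_sd = noise_sd),
              class = "lh_contaminated")
  })
}

## Translate a binary mask, dropping parts shifted outside the grid.
translate_mask <- function(mask, shift) {
  d <- img_dim(mask)
  out <- array(0L, d)
  src <- dst <- vector("list", length(d))
  for (a in seq_along(d)) {
    s <- shift[a]
    src[[a]] <- max(1L, 1L - s):min(d[a], d[a] - s)
    dst[[a]] <- src[[a]] + s
  }
  block <- do.call(`[`, c(list(mask), src, list(drop = FALSE)))
  do.call(`[<-`, c(list(out), dst, list(value = block)))
}

#' Uniform-noise image (far-out-of-distribution fixture)
#'
#' @param rng_seed Integer seed.
#' @param size Grid shape.
#' @return Array with i.i.d. uniform \[0,1\] values.
#' @export
noise_image <- function(rng_seed, size = c(64, 64)) {
  with_seed(rng_seed, array(stats::runif(prod(size)), as.integer(size)))
}

#' Write a synthetic dataset to disk
#'
#' Generates phantoms (train/val splits) and sprite-contaminated phantoms
#' (test split) and writes them as PNG (2D) or NIfTI (3D) alongside a
#' `manifest.csv` describing each sample.
#'
#' @param dir Output directory (created if needed).
#' @param n_train,n_val,n_test Split sizes.
#' @param size Image shape.
#' @param seed Base seed; every sample derives its own seed from it.
#' @param intensities Candidate sprite intensities for the test split
#'   (sampled uniformly per test image; default the binary 0/1 design).
#' @param noise_sd Additive Gaussian noise on sprite pixels (test split).
#' @return A tibble manifest (also written as `manifest.csv`), invisibly.
#' @export
make_synthetic_dataset <- function(dir, n_train = 200, n_val = 50, n_test = 50,
                                   size = c(64, 64), seed = 1,
                                   intensities = c(0, 1), noise_sd = 0) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ext <- if (length(size) == 2L) ".png" else ".nii.gz"
  rows <- list()
  write_one <- function(img, name) {
    path <- file.path(dir, paste0(name, ext))
    write_image(img, path)
    basename(path)
  }
  k <- 0L
  for (split in c("train", "val")) {
    n <- if (split == "train") n_train else n_val
    for (i in seq_len(n)) {
      k <- k + 1L
      s <- derive_seed(seed, k)
      ph <- generate_phantom(s, size)
      f <- write_one(ph$image, sprintf("%s_%04d", split, i))
      rows[[k]] <- tibble::tibble(id = sprintf("%s_%04d", split, i),
                                  split = split, seed = s, file = f,
                                  intensity = NA_real_, noise_sd = NA_real_,
                                  gt_file = NA_character_)
    }
  }
  for (i in seq_len(n_test)) {
    k <- k + 1L
    s <- derive_seed(seed, k)
    ph <- generate_phantom(s, size)
    shp <- c("ellipse", "square", "blob")[1L + (i %% 3L)]
    spr <- generate_sprite(derive_seed(s, 1), size, shp)
    inten <- intensities[1L + (i %% length(intensities))]
    cs <- contaminate(ph, spr, inten, noise_sd, rng_seed = derive_seed(s, 2))
    f <- write_one(cs$image, sprintf("test_%04d", i))
    g <- write_one(cs$gt_mask, sprintf("test_%04d_gt", i))
    rows[[k]] <- tibble::tibble(id = sprintf("test_%04d", i), split = "test",
                                seed = s, file = f, intensity = inten,
                                noise_sd = noise_sd, gt_file = g)
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}
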