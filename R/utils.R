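#' @keywords internal
"_PACKAGE"

## Internal helpers shared across modules. All generators in the package are
## pure functions of an explicit seed: `with_seed()` evaluates an expression
## under a temporary RNG state and restores the caller's state afterwards.

with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

## Deterministic child seeds, kept below 2^31 so they remain valid R integers.
derive_seed <- function(seed, salt) {
  (as.double(seed) * 7919 + as.double(salt) * 104729 + 12345) %% 2147483629
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

img_dim <- function(x) {
  d <- dim(x)
  if (is.null(d)) stop("expected a matrix or array image, got a vector")
  d
}

## Reflect (mirror) indices used for edge padding: 1,2,...,n,n,n-1,...
reflect_index <- function(i, n) {
  i <- ((i - 1L) %% (2L * n)) + 1L
  ifelse(i > n, 2L * n + 1L - i, i)
}

## Shift an array along one axis with reflected edges.
shift_axis <- function(x, axis, offset) {
  d <- dim(x)
  idx <- rep(list(quote(expr = )), length(d))
  idx[[axis]] <- reflect_index(seq_len(d[axis]) + offset, d[axis])
  do.call(`[`, c(list(x), idx, list(drop = FALSE)))
}

#' Separable Gaussian smoothing of a 2D or 3D array
#'
#' Convolves each axis with a normalized Gaussian kernel (radius
#' `ceiling(3*sigma)`), using mirror padding so that a constant input is
#' returned exactly unchanged.
#'
#' @param x Numeric matrix or 3D array.
#' @param sigma Gaussian standard deviation in pixels. `sigma = 0` returns
#'   `x` unchanged.
#' @return Array of the same shape as `x`.
#' @export
gaussian_smooth <- function(x, sigma) {
  stopifnot(is.numeric(sigma), length(sigma) == 1L, sigma >= 0)
  if (sigma == 0) return(x)
  d <- img_dim(x)
  r <- as.integer(ceiling(3 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k <- k / sum(k)
  out <- x
  for (axis in seq_along(d)) {
    acc <- array(0, d)
    for (j in seq_along(k)) {
      acc <- acc + k[j] * shift_axis(out, axis, j - r - 1L)
    }
    out <- acc
  }
  out
}

## Nearest-neighbour upsampling: each cell becomes an f^ndim block.
upsample_nearest <- function(x, f) {
  d <- img_dim(x)
  idx <- lapply(d, function(n) rep(seq_len(n), each = f))
  do.call(`[`, c(list(x), idx, list(drop = FALSE)))
}

## Average-pool an array by factor f along every axis (inverse of the above
## in shape); used to compare image-space masks against latent grids.
downsample_mean <- function(x, f) {
  d <- img_dim(x)
  stopifnot(all(d %% f == 0))
  if (length(d) == 2L) {
    out <- matrix(0, d[1] %/% f, d[2] %/% f)
    for (a in seq_len(f)) for (b in seq_len(f)) {
      out <- out + x[seq(a, d[1], by = f), seq(b, d[2], by = f)]
    }
    return(out / f^2)
  }
  out <- array(0, d %/% f)
  for (a in seq_len(f)) for (b in seq_len(f)) for (c in seq_len(f)) {
    out <- out + x[seq(a, d[1], by = f), seq(b, d[2], by = f),
                   seq(c, d[3], by = f)]
  }
  out / f^3
}

## Connected component labelling (face connectivity) for binary 2D/3D masks,
## via iterative flood fill. Small grids only; used by the sprite generator
## and its tests.
label_components <- function(mask) {
  d <- img_dim(mask)
  lab <- array(0L, d)
  mask <- mask > 0
  offsets <- diag(length(d))
  offsets <- rbind(offsets, -offsets)
  lin <- which(mask)
  if (!length(lin)) return(lab)
  coords <- arrayInd(lin, d)
  strides <- cumprod(c(1L, d[-length(d)]))
  current <- 0L
  for (start in lin) {
    if (lab[start] != 0L) next
    current <- current + 1L
    queue <- start
    lab[start] <- current
    while (length(queue)) {
      p <- queue[length(queue)]
      queue <- queue[-length(queue)]
      pc <- arrayInd(p, d)[1, ]
      for (o in seq_len(nrow(offsets))) {
        q <- pc + offsets[o, ]
        if (any(q < 1L) || any(q > d)) next
        ql <- as.integer(1 + sum((q - 1) * strides))
        if (mask[ql] && lab[ql] == 0L) {
          lab[ql] <- current
          queue <- c(queue, ql)
        }
      }
    }
  }
  lab
}

is_connected <- function(mask) {
  lab <- label_components(mask)
  max(lab) <= 1L
}

#' Read a grayscale image (PNG or NIfTI) as a numeric array in [0,1]
#'
#' @param path File path; `.png` is read with the png package (first channel
#'   if multi-channel), `.nii`/`.nii.gz` with RNifti.
#' @param normalize One of `"none"`, `"minmax"`, `"percentile"` (1st/99th
#'   percentile scaling, clipped to \[0,1\]).
#' @return Numeric matrix (2D) or array (3D).
#' @export
read_image <- function(path, normalize = c("none", "minmax", "percentile")) {
  normalize <- match.arg(normalize)
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    x <- png::readPNG(path)
    if (length(dim(x)) == 3L) x <- x[, , 1]
  } else if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    x <- as.array(RNifti::readNifti(path))
  } else {
    stop("unsupported image format: ", path)
  }
  normalize_image(x, normalize)
}

#' Write a grayscale image as PNG (2D) or NIfTI (3D)
#'
#' @param x Numeric matrix or 3D array in \[0,1\].
#' @param path Output path; format chosen from the extension.
#' @return `path`, invisibly.
#' @export
write_image <- function(x, path) {
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    stopifnot(length(img_dim(x)) == 2L)
    png::writePNG(clip01(x), path)
  } else if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    RNifti::writeNifti(RNifti::asNifti(x), path)
  } else {
    stop("unsupported image format: ", path)
  }
  invisible(path)
}

#' Rescale image intensities to [0,1]
#'
#' `"minmax"` maps the observed range onto \[0,1\]; `"percentile"` scales by
#' the 1st and 99th intensity percentiles and clips, the convention for 3D
#' volumes. `"none"` only clips.
#'
#' @param x Numeric array.
#' @param method One of `"none"`, `"minmax"`, `"percentile"`.
#' @return Array of the same shape, values in \[0,1\].
#' @export
normalize_image <- function(x, method = c("none", "minmax", "percentile")) {
  method <- match.arg(method)
  if (method == "minmax") {
    rng <- range(x)
    if (diff(rng) > 0) x <- (x - rng[1]) / diff(rng)
  } else if (method == "percentile") {
    q <- stats::quantile(x, c(0.01, 0.99), names = FALSE)
    if (diff(q) > 0) x <- (x - q[1]) / diff(q)
  }
  clip01(x)
}
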