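## Orderings: bijections between the latent index grid and 1D token
## sequences. An ordering is stored as the visit order `perm` of linear
## (column-major) grid indices plus the descriptor that reproduces it, so
## checkpoints serialize the descriptor, never the raw permutation.

new_ordering <- function(class, shape, perm, reflect, transpose, seed = NULL) {
  shape <- as.integer(shape)
  stopifnot(length(perm) == prod(shape), !anyDuplicated(perm))
  inv <- integer(length(perm))
  inv[perm] <- seq_along(perm)
  structure(list(
    class = class, shape = shape,
    reflect = reflect, transpose = as.integer(transpose),
    seed = seed, perm = as.integer(perm), inv = inv,
    name = paste0(class, "[", paste(shape, collapse = "x"), "]",
                  ";refl=", paste(as.integer(reflect), collapse = ""),
                  ";perm=", paste(transpose, collapse = ""),
                  if (!is.null(seed)) paste0(";seed=", seed) else "")
  ), class = "lh_ordering")
}

#' @export
print.lh_ordering <- function(x, ...) {
  cat("<lh_ordering>", x$name, "\n")
  invisible(x)
}

## Convert a path of 1-based grid coordinates (n x ndim matrix, visit order)
## into a permutation of linear column-major indices, after applying the
## descriptor's axis permutation and reflections to the coordinates.
path_to_perm <- function(coords, shape, reflect, transpose) {
  nd <- length(shape)
  full <- matrix(0L, nrow(coords), nd)
  ## traversal was generated on shape[transpose]; coordinate j of the
  ## traversal lives on grid axis transpose[j]
  for (j in seq_len(nd)) full[, transpose[j]] <- coords[, j]
  for (a in seq_len(nd)) {
    if (reflect[a]) full[, a] <- shape[a] + 1L - full[, a]
  }
  strides <- cumprod(c(1L, shape[-nd]))
  as.integer(1 + full %*% strides - sum(strides))
}

check_ordering_args <- function(shape, reflect, transpose) {
  nd <- length(shape)
  if (is.null(reflect)) reflect <- rep(FALSE, nd)
  if (is.null(transpose)) transpose <- seq_len(nd)
  stopifnot(length(reflect) == nd)
  if (!identical(sort(as.integer(transpose)), seq_len(nd))) {
    stop("transpose must be a permutation of the grid axes")
  }
  list(reflect = as.logical(reflect), transpose = as.integer(transpose))
}

## Row-major coordinate path (last axis fastest) over a grid.
raster_path <- function(shape) {
  g <- do.call(expand.grid, lapply(rev(shape), seq_len))
  as.matrix(g[, rev(seq_along(shape)), drop = FALSE])
}

## Boustrophedon: row-major, but each axis after the first alternates
## direction with the parity of its enclosing counter.
snake_path <- function(shape) {
  if (length(shape) == 1L) return(matrix(seq_len(shape), ncol = 1))
  sub <- snake_path(shape[-1])
  rev_sub <- sub[rev(seq_len(nrow(sub))), , drop = FALSE]
  out <- lapply(seq_len(shape[1]), function(i) {
    block <- if (i %% 2L == 1L) sub else rev_sub
    cbind(i, block)
  })
  do.call(rbind, unname(out))
}

#' Raster (row-major) ordering of a latent grid
#'
#' Traverses the grid row-major (last axis fastest), optionally after
#' reflecting axes and/or permuting them ("transposition"); these variants
#' build the ordering ensemble.
#'
#' @param grid_shape Integer vector, the latent grid shape.
#' @param reflect Logical per-axis reflection flags.
#' @param transpose Integer axis permutation (e.g. `c(2, 1)` for the 90
#'   degree variant in 2D).
#' @return An `lh_ordering`.
#' @export
raster_ordering <- function(grid_shape, reflect = NULL, transpose = NULL) {
  a <- check_ordering_args(grid_shape, reflect, transpose)
  coords <- raster_path(grid_shape[a$transpose])
  perm <- path_to_perm(coords, grid_shape, a$reflect, a$transpose)
  new_ordering("raster", grid_shape, perm, a$reflect, a$transpose)
}

#' S-curve (boustrophedon) ordering
#'
#' Like raster, but alternating the traversal direction of each inner axis so
#' consecutive sequence positions are always grid-adjacent.
#'
#' @inheritParams raster_ordering
#' @return An `lh_ordering`.
#' @export
s_curve_ordering <- function(grid_shape, reflect = NULL, transpose = NULL) {
  a <- check_ordering_args(grid_shape, reflect, transpose)
  coords <- snake_path(grid_shape[a$transpose])
  perm <- path_to_perm(coords, grid_shape, a$reflect, a$transpose)
  new_ordering("s_curve", grid_shape, perm, a$reflect, a$transpose)
}

#' Generalized Hilbert (space-filling curve) ordering
#'
#' Uses a generalized Hilbert construction valid for arbitrary (also
#' non-power-of-two, anisotropic) rectangles. In 3D the curve is built from
#' per-layer 2D curves traversed boustrophedon across layers, which keeps
#' every step a unit grid move on even-sided grids while covering arbitrary
#' box shapes.
#'
#' @inheritParams raster_ordering
#' @return An `lh_ordering`.
#' @export
hilbert_ordering <- function(grid_shape, reflect = NULL, transpose = NULL) {
  a <- check_ordering_args(grid_shape, reflect, transpose)
  shp <- grid_shape[a$transpose]
  coords <- if (length(shp) == 2L) gilbert2d(shp) else gilbert3d(shp)
  perm <- path_to_perm(coords, grid_shape, a$reflect, a$transpose)
  new_ordering("hilbert", grid_shape, perm, a$reflect, a$transpose)
}

#' Random ordering
#'
#' A uniformly drawn permutation of the grid cells, reproducible by seed.
#'
#' @inheritParams raster_ordering
#' @param seed Integer seed for the permutation.
#' @return An `lh_ordering`.
#' @export
random_ordering <- function(grid_shape, seed = 0, reflect = NULL,
                            transpose = NULL) {
  a <- check_ordering_args(grid_shape, reflect, transpose)
  base <- with_seed(seed, sample.int(prod(grid_shape)))
  coords0 <- arrayInd(base, grid_shape[a$transpose])
  perm <- path_to_perm(coords0, grid_shape, a$reflect, a$transpose)
  new_ordering("random", grid_shape, perm, a$reflect, a$transpose, seed = seed)
}

make_ordering <- function(class, grid_shape, reflect = NULL, transpose = NULL,
                          seed = 0) {
  switch(class,
    raster = raster_ordering(grid_shape, reflect, transpose),
    s_curve = s_curve_ordering(grid_shape, reflect, transpose),
    hilbert = hilbert_ordering(grid_shape, reflect, transpose),
    random = random_ordering(grid_shape, seed, reflect, transpose),
    stop("unknown ordering class: ", class))
}

#' Flatten a latent grid into a token sequence / restore it
#'
#' `apply_ordering()` reads the grid cells in the ordering's visit order;
#' `invert_ordering()` writes a sequence back into grid shape. They are
#' mutually inverse for every ordering.
#'
#' @param grid Array of the ordering's `shape` (token indices or any values).
#' @param ordering An `lh_ordering`.
#' @return `apply_ordering`: a vector of length `prod(shape)`;
#'   `invert_ordering`: an array of shape `shape`.
#' @export
apply_ordering <- function(grid, ordering) {
  stopifnot(inherits(ordering, "lh_ordering"),
            all(img_dim(grid) == ordering$shape))
  as.vector(grid)[ordering$perm]
}

#' @rdname apply_ordering
#' @param sequence Vector of length `prod(shape)`.
#' @export
invert_ordering <- function(sequence, ordering) {
  stopifnot(inherits(ordering, "lh_ordering"),
            length(sequence) == prod(ordering$shape))
  out <- sequence
  out[ordering$perm] <- sequence
  array(out, ordering$shape)
}

#' Build an ensemble of distinct orderings
#'
#' 2D default: the 4 reflection combinations crossed with transposition,
#' 8 orderings. 3D default: identity plus the 6 single- and double-axis
#' reflections, 7 orderings, no axis permutation. For the `"random"` class
#' the ensemble uses `count` distinct seeds instead.
#'
#' @param class Ordering class (`"raster"`, `"s_curve"`, `"hilbert"`,
#'   `"random"`).
#' @param grid_shape Latent grid shape (length 2 or 3).
#' @param count Number of orderings (2D default 8, 3D default 7).
#' @param seed Base seed (random class only).
#' @return List of `lh_ordering`, pairwise distinct permutations.
#' @export
ensemble_orderings <- function(class = "raster", grid_shape,
                               count = if (length(grid_shape) == 2L) 8L else 7L,
                               seed = 0) {
  nd <- length(grid_shape)
  if (class == "random") {
    out <- lapply(seq_len(count),
                  function(i) random_ordering(grid_shape,
                                              seed = derive_seed(seed, i)))
  } else if (nd == 2L) {
    variants <- list()
    for (tr in list(c(1L, 2L), c(2L, 1L))) {
      for (r1 in c(FALSE, TRUE)) for (r2 in c(FALSE, TRUE)) {
        variants[[length(variants) + 1L]] <- list(reflect = c(r1, r2),
                                                  transpose = tr)
      }
    }
    if (count > length(variants)) stop("at most 8 ensemble members in 2D")
    out <- lapply(variants[seq_len(count)], function(v) {
      make_ordering(class, grid_shape, v$reflect, v$transpose)
    })
  } else {
    refl <- list(c(FALSE, FALSE, FALSE),
                 c(TRUE, FALSE, FALSE), c(FALSE, TRUE, FALSE),
                 c(FALSE, FALSE, TRUE), c(TRUE, TRUE, FALSE),
                 c(TRUE, FALSE, TRUE), c(FALSE, TRUE, TRUE))
    if (count > length(refl)) stop("at most 7 default ensemble members in 3D")
    out <- lapply(refl[seq_len(count)], function(r) {
      make_ordering(class, grid_shape, r, seq_len(nd))
    })
  }
  perms <- vapply(out, function(o) paste(o$perm, collapse = ","), "")
  if (anyDuplicated(perms)) stop("ensemble orderings are not distinct")
  out
}

## ---- generalized Hilbert construction (arbitrary rectangles/boxes) -------

sgn <- function(x) sign(x)

gilbert2d <- function(shape) {
  ## shape = c(rows, cols); generate on (width = cols, height = rows) and
  ## read (x, y) back as (col, row) so the 2x2 curve starts down the rows.
  w <- shape[2]; h <- shape[1]
  acc <- matrix(0L, w * h, 2)
  env <- new.env()
  env$k <- 0L
  emit <- function(x, y) {
    env$k <- env$k + 1L
    acc[env$k, ] <<- c(y + 1L, x + 1L)  # (row, col), 1-based
  }
  if (w >= h) gen2d(0L, 0L, w, 0L, 0L, h, emit)
  else gen2d(0L, 0L, 0L, h, w, 0L, emit)
  acc
}

gen2d <- function(x, y, ax, ay, bx, by, emit) {
  w <- abs(ax + ay); h <- abs(bx + by)
  dax <- sgn(ax); day <- sgn(ay); dbx <- sgn(bx); dby <- sgn(by)
  if (h == 1) {
    for (i in seq_len(w)) { emit(x, y); x <- x + dax; y <- y + day }
    return(invisible())
  }
  if (w == 1) {
    for (i in seq_len(h)) { emit(x, y); x <- x + dbx; y <- y + dby }
    return(invisible())
  }
  ax2 <- ax %/% 2L; ay2 <- ay %/% 2L
  bx2 <- bx %/% 2L; by2 <- by %/% 2L
  w2 <- abs(ax2 + ay2); h2 <- abs(bx2 + by2)
  if (2 * w > 3 * h) {
    if (w2 %% 2 && w > 2) { ax2 <- ax2 + dax; ay2 <- ay2 + day }
    gen2d(x, y, ax2, ay2, bx, by, emit)
    gen2d(x + ax2, y + ay2, ax - ax2, ay - ay2, bx, by, emit)
  } else {
    if (h2 %% 2 && h > 2) { bx2 <- bx2 + dbx; by2 <- by2 + dby }
    gen2d(x, y, bx2, by2, ax2, ay2, emit)
    gen2d(x + bx2, y + by2, ax, ay, bx - bx2, by - by2, emit)
    gen2d(x + (ax - dax) + (bx2 - dbx), y + (ay - day) + (by2 - dby),
          -bx2, -by2, -(ax - ax2), -(ay - ay2), emit)
  }
}

## 3D generalized Hilbert: 2D curves per layer, layers traversed
## boustrophedon (the in-layer path reverses on alternate layers, so the
## step between layers is a single unit move along the third axis).
gilbert3d <- function(shape) {
  layer <- gilbert2d(shape[1:2])
  layer_rev <- layer[rev(seq_len(nrow(layer))), , drop = FALSE]
  out <- lapply(seq_len(shape[3]), function(k) {
    p <- if (k %% 2L == 1L) layer else layer_rev
    cbind(p, k)
  })
  do.call(rbind, unname(out))
}

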