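coords0 <- function(o) arrayInd(o$perm, o$shape) - 1L

test_that("raster ordering visits the grid row-major", {
  o <- raster_ordering(c(2, 2))
  expect_equal(coords0(o), rbind(c(0, 0), c(0, 1), c(1, 0), c(1, 1)))
  ob <- raster_ordering(c(2, 2), reflect = c(TRUE, TRUE))
  expect_equal(coords0(ob), rbind(c(1, 1), c(1, 0), c(0, 1), c(0, 0)))
})

test_that("s-curve ordering alternates row direction and stays adjacent", {
  o <- s_curve_ordering(c(2, 3))
  expect_equal(coords0(o), rbind(c(0, 0), c(0, 1), c(0, 2),
                                 c(1, 2), c(1, 1), c(1, 0)))
  for (shape in list(c(4, 7), c(5, 5), c(3, 4, 5))) {
    oo <- s_curve_ordering(shape)
    steps <- abs(diff(coords0(oo)))
    expect_true(all(rowSums(steps) == 1), label = paste(shape, collapse = "x"))
  }
})

test_that("hilbert ordering gives the canonical first-order 2x2 curve", {
  o <- hilbert_ordering(c(2, 2))
  expect_equal(coords0(o), rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)))
})

test_that("hilbert paths are grid-adjacent on even-sided grids", {
  for (shape in list(c(8, 8), c(4, 8), c(6, 10), c(4, 4, 4), c(4, 6, 8))) {
    o <- hilbert_ordering(shape)
    steps <- abs(diff(coords0(o)))
    expect_true(all(rowSums(steps) == 1), label = paste(shape, collapse = "x"))
  }
})

test_that("hilbert locality beats raster on a square grid", {
  ## typical (median) sequence-index distance over grid-adjacent cell pairs;
  ## the mean is dominated by the few long wrap-around jumps every
  ## space-filling curve must make, so the median is the meaningful
  ## locality statistic
  neighbour_span <- function(o) {
    pos <- o$inv
    d <- o$shape
    spans <- c()
    for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
      a <- (j - 1) * d[1] + i
      if (j < d[2]) spans <- c(spans, abs(pos[a] - pos[a + d[1]]))
      if (i < d[1]) spans <- c(spans, abs(pos[a] - pos[a + 1]))
    }
    spans
  }
  expect_lt(median(neighbour_span(hilbert_ordering(c(8, 8)))),
            median(neighbour_span(raster_ordering(c(8, 8)))))
  ## and more consecutive-adjacent pairs overall
  expect_gt(mean(neighbour_span(hilbert_ordering(c(8, 8))) == 1),
            mean(neighbour_span(raster_ordering(c(8, 8))) == 1))
})

test_that("random orderings are seed-reproducible and seed-sensitive", {
  a <- random_ordering(c(4, 4), seed = 3)
  b <- random_ordering(c(4, 4), seed = 3)
  expect_identical(a$perm, b$perm)
  c <- random_ordering(c(4, 4), seed = 4)
  expect_false(identical(a$perm, c$perm))
})

test_that("every ordering class is a bijection over random shapes", {
  shapes2 <- list(c(2, 2), c(3, 5), c(7, 4), c(16, 16), c(9, 13))
  shapes3 <- list(c(2, 2, 2), c(3, 4, 5), c(8, 8, 8), c(6, 3, 7))
  for (shape in c(shapes2, shapes3)) {
    for (cls in c("raster", "s_curve", "hilbert", "random")) {
      o <- latentheal:::make_ordering(cls, shape, seed = 11)
      expect_identical(sort(o$perm), seq_len(prod(shape)),
                       label = paste(cls, paste(shape, collapse = "x")))
      expect_identical(o$inv[o$perm], seq_len(prod(shape)))
    }
  }
})

test_that("apply and invert are mutually inverse for all classes", {
  for (shape in list(c(4, 4), c(3, 5), c(4, 4, 4))) {
    g <- random_grid(shape, seed = 5)
    for (cls in c("raster", "s_curve", "hilbert", "random")) {
      o <- latentheal:::make_ordering(cls, shape, seed = 2)
      expect_identical(invert_ordering(apply_ordering(g, o), o), g,
                       label = paste(cls, paste(shape, collapse = "x")))
    }
  }
})

test_that("raster flattening matches the worked 2x2 example", {
  g <- matrix(c(5, 2, 7, 9), 2, 2)  # rows: (5,7) / (2,9)
  o <- raster_ordering(c(2, 2))
  expect_equal(apply_ordering(g, o), c(5, 7, 2, 9))
  ob <- raster_ordering(c(2, 2), reflect = c(TRUE, TRUE))
  back <- invert_ordering(c(5, 7, 2, 9), ob)
  expect_equal(back, matrix(c(9, 7, 2, 5), 2, 2))  # rows: (9,2) / (7,5)
})

test_that("reflected orderings equal reflecting the grid first", {
  g <- random_grid(c(4, 6), seed = 9)
  base <- s_curve_ordering(c(4, 6))
  refl <- s_curve_ordering(c(4, 6), reflect = c(TRUE, FALSE))
  g_flipped <- g[rev(seq_len(4)), ]
  expect_equal(apply_ordering(g, refl), apply_ordering(g_flipped, base))
})

test_that("ensembles contain the advertised number of distinct orderings", {
  o2 <- ensemble_orderings("raster", c(8, 8), 8)
  expect_length(o2, 8)
  keys <- vapply(o2, function(o) paste(o$perm, collapse = ","), "")
  expect_equal(anyDuplicated(keys), 0L)
  o3 <- ensemble_orderings("raster", c(4, 4, 4), 7)
  expect_length(o3, 7)
  keys3 <- vapply(o3, function(o) paste(o$perm, collapse = ","), "")
  expect_equal(anyDuplicated(keys3), 0L)
  for (o in c(o2, o3)) {
    expect_identical(sort(o$perm), seq_len(prod(o$shape)))
  }
})

test_that("shape or permutation mismatches are rejected", {
  o <- raster_ordering(c(4, 4))
  expect_error(apply_ordering(matrix(0, 3, 4), o))
  expect_error(invert_ordering(1:5, o))
  expect_error(raster_ordering(c(4, 4), transpose = c(1, 1)), "permutation")
})
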