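# brute-force even-odd point-in-polygon oracle, written independently of
# the scanline rasterizer: casts a ray in +x from each pixel centre
pipOracle <- function(points, image_size) {
  H <- image_size[1]; W <- image_size[2]
  out <- matrix(0L, H, W)
  n <- nrow(points)
  for (r in seq_len(H)) for (cl in seq_len(W)) {
    px <- cl - 0.5; py <- r - 0.5
    inside <- FALSE
    j <- n
    for (i in seq_len(n)) {
      xi <- points[i, 1]; yi <- points[i, 2]
      xj <- points[j, 1]; yj <- points[j, 2]
      if ((yi > py) != (yj > py) &&
          px < (xj - xi) * (py - yi) / (yj - yi) + xi)
        inside <- !inside
      j <- i
    }
    if (inside) out[r, cl] <- 1L
  }
  out
}

test_that("scanline rasterization matches the point-in-polygon oracle", {
  # axis-aligned square
  sq <- cbind(c(3, 11, 11, 3), c(2, 2, 9, 9))
  m <- rasterizePolygon(sq, c(16, 16))
  expect_equal(m, pipOracle(sq, c(16, 16)))
  expect_equal(sum(m), 8 * 7)          # side lengths 8 x 7 in pixels
  # irregular convex and concave polygons
  for (pts in list(cbind(c(1, 14, 8), c(1, 4, 14)),
                   cbind(c(2, 14, 14, 8, 2), c(2, 2, 12, 6, 12)))) {
    expect_equal(rasterizePolygon(pts, c(16, 16)),
                 pipOracle(pts, c(16, 16)))
  }
})

test_that("LabelMe documents rasterize with union semantics", {
  doc <- list(imageHeight = 12, imageWidth = 12, shapes = list(
    list(label = "grain",
         points = list(c(1, 1), c(6, 1), c(6, 6), c(1, 6))),
    list(label = "grain",
         points = list(c(4, 4), c(9, 4), c(9, 9), c(4, 9))),
    list(label = "dish",
         points = list(c(0, 0), c(12, 0), c(12, 12), c(0, 12)))))
  m <- parseLabelMe(doc)
  a <- rasterizePolygon(do.call(rbind, doc$shapes[[1]]$points), c(12, 12))
  b <- rasterizePolygon(do.call(rbind, doc$shapes[[2]]$points), c(12, 12))
  expect_equal(m, pmax(a, b))          # overlap counted once
  expect_lt(sum(m), sum(a) + sum(b))   # the union is smaller than the sum
})

test_that("degenerate and unknown shapes are handled", {
  empty <- list(imageHeight = 8, imageWidth = 8, shapes = list())
  expect_equal(sum(parseLabelMe(empty)), 0)

  bad <- list(imageHeight = 8, imageWidth = 8, shapes = list(
    list(label = "grain", points = list(c(1, 1), c(2, 2)))))
  expect_error(parseLabelMe(bad), "fewer than 3")

  odd <- list(imageHeight = 8, imageWidth = 8, shapes = list(
    list(label = "blob",
         points = list(c(1, 1), c(5, 1), c(5, 5)))))
  expect_warning(m <- parseLabelMe(odd), "unknown label")
  expect_equal(sum(m), 0)
})
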