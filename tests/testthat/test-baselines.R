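test_that("Hough voting peaks on the true vertex-form parameters", {
  # truth on exact grid nodes: x0 = 10, y0 = 16, a = 4
  truth_a <- 4; truth_x0 <- 10; truth_y0 <- 16
  p <- parabola(1 / (4 * truth_a), -truth_y0 / (2 * truth_a),
                truth_y0^2 / (4 * truth_a) + truth_x0)
  img <- rasterize(p, 32, 32)
  grid <- hough_grid(x0_values = seq(0, 30, by = 2),
                     y0_values = seq(0, 30, by = 4),
                     a_values = c(-8, -4, 4, 8))
  res <- detect_parabola_hough(img, grid)
  va <- vertex_aperture(res$parabola)
  expect_equal(va$vertex_x, truth_x0)
  expect_equal(va$vertex_y, truth_y0)
  expect_equal(va$four_p, 4 * truth_a)

  expect_error(hough_grid(numeric(0), 1, 1))
  expect_error(hough_grid(1, 1, 0))
})

test_that("accumulator votes match an exhaustive triple-loop oracle", {
  set.seed(41)
  img <- random_binary_image(32, 32, density = 0.08)
  grid <- hough_grid(x0_values = seq(0, 31, by = 3),
                     y0_values = seq(0, 31, by = 3),
                     a_values = c(-6, -3, 3, 6))
  res <- detect_parabola_hough(img, grid)

  oracle <- array(0L, dim = c(length(grid$x0_values),
                              length(grid$y0_values),
                              length(grid$a_values)))
  half <- 1.5  # half the x0 spacing
  for (n in seq_len(img$N)) {
    x <- img$foreground[n, "x"]; y <- img$foreground[n, "y"]
    for (ia in seq_along(grid$a_values)) {
      for (iy in seq_along(grid$y0_values)) {
        x0 <- x - (y - grid$y0_values[iy])^2 / (4 * grid$a_values[ia])
        d <- abs(x0 - grid$x0_values)
        ix <- which.min(d)
        if (d[ix] <= half) oracle[ix, iy, ia] <- oracle[ix, iy, ia] + 1L
      }
    }
  }
  expect_equal(res$accumulator, oracle)

  # total votes are invariant to pixel ordering (voting is per-pixel)
  shuffled <- img$grid[, ]
  expect_equal(sum(detect_parabola_hough(edge_image(shuffled),
                                         grid)$accumulator),
               sum(res$accumulator))
})

test_that("RANSAC finds a noise-free planted parabola and is reproducible", {
  p <- parabola(0.04, -2, 40)
  img <- rasterize(p, 64, 80)
  res <- detect_parabola_ransac(img, ransac_params(iterations = 300, seed = 6))
  expect_equal(res$fitness, img$N)  # every planted pixel is an inlier

  res2 <- detect_parabola_ransac(img, ransac_params(iterations = 300, seed = 6))
  expect_identical(res$parabola, res2$parabola)
  expect_identical(res$fitness, res2$fitness)

  # reported inlier count is reproducible by recounting against the model
  px <- img$foreground[, "x"]; py <- img$foreground[, "y"]
  r <- abs(px - parabola_eval(res$parabola, py))
  expect_equal(sum(r <= 2.0), res$fitness)

  expect_error(detect_parabola_ransac(matrix(0L, 5, 5)),
               class = "empty_image_error")
})

test_that("RANSAC sampling replays exactly from its seed", {
  set.seed(42)
  img <- random_binary_image(30, 40, density = 0.05, min_fg = 10)
  params <- ransac_params(iterations = 200, inlier_tolerance = 1.5, seed = 77)
  res <- detect_parabola_ransac(img, params)

  # replay the identical sample stream and score each triplet independently
  set.seed(77)
  px <- img$foreground[, "x"]; py <- img$foreground[, "y"]
  best <- -1L
  for (it in 1:200) {
    s <- sample.int(img$N, 3)
    cf <- tryCatch(solve_fit_oracle(cbind(px[s], py[s])),
                   error = function(e) NULL)
    if (is.null(cf) || !all(is.finite(cf)) || abs(cf[1]) < 1e-12) next
    best <- max(best, sum(abs(px - (cf[1] * py^2 + cf[2] * py + cf[3])) <= 1.5))
  }
  # the refit model can only keep or improve the consensus
  expect_gte(res$fitness, best)
})

test_that("all three detectors agree on a clean planted curve", {
  truth_a <- 8; truth_x0 <- 20; truth_y0 <- 32
  p <- parabola(1 / (4 * truth_a), -truth_y0 / (2 * truth_a),
                truth_y0^2 / (4 * truth_a) + truth_x0)
  img <- rasterize(p, 64, 64)
  truth_raster <- img$grid

  umda <- detect_parabola_umda(img, umda_params(seed = 3))
  ransac <- detect_parabola_ransac(img, ransac_params(iterations = 500, seed = 3))
  hough <- detect_parabola_hough(img, hough_grid(seq(0, 62, 2), seq(0, 62, 2),
                                                 c(-8, -4, 4, 8)))
  # Hough reads the truth off its grid node and the RANSAC refit uses all
  # pixels: both reproduce the planted raster exactly
  expect_equal(rasterize(ransac$parabola, 64, 64)$grid, truth_raster)
  expect_equal(rasterize(hough$parabola, 64, 64)$grid, truth_raster)
  # the UMDA fit interpolates three *rounded* raster pixels, so its curve
  # matches the planted raster up to rounding of the remaining rows
  expect_gte(umda$fitness, 0.95 * img$N)
  expect_gte(overlap_fraction(p, umda$parabola, 64, 64, tol = 1), 0.95)
})
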