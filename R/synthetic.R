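#' Generate a ground-truthed synthetic edge scene
#'
#' Renders the evaluation scene used throughout the benchmark protocol:
#' one sideways parabola `x = A y^2 + B y + C` with coefficients drawn
#' at random, among randomly placed straight-line and circle
#' distractors, on a binary frame.  The planted coefficients are
#' recorded exactly as drawn, so ground truth is exact: at zero noise
#' the planted curve's Hadamard fitness equals its in-frame pixel count.
#'
#' Coefficients are drawn through the vertex parameterization (aperture
#' `4p = 1/A`, vertex position), then redrawn until the in-frame raster
#' has between `min_pixels` and `max_pixels` pixels so every scene
#' carries a comparable amount of curve evidence.  After composing the
#' thin shapes the whole scene is dilated with a Euclidean disk of
#' radius `thickness` (default 3), reproducing the thick edge bands that
#' the conditioning chain's dilation stage produces on real inputs; set
#' `thickness = 0` for the bare 1-pixel rasters.  Distractor line
#' segments are length-bounded so the planted curve remains the
#' dominant structure and the ground-truth fitness optimum.
#'
#' @param height,width Frame size in pixels (defaults 512 x 512).
#' @param n_lines,n_circles Number of distractor lines (default 3) and
#'   circles (default 2).
#' @param coeff_ranges List of ranges for the random draw:
#'   `abs_A` (magnitude of the quadratic coefficient; sign is a fair
#'   coin), `vertex_t` (vertex quadratic-argument, i.e. row, range) and
#'   `vertex_s` (vertex column range).
#' @param min_pixels,max_pixels Accepted in-frame pixel count of the
#'   planted curve (defaults 100 and 500).
#' @param thickness Disk radius of the final scene dilation (default 3).
#' @param seed Optional integer seed; scenes are reproducible bit for
#'   bit.
#' @return A list of class `"synthetic_scene"`: `image` (an
#'   [edge_image()]), `truth` (the planted [parabola()]), `distractors`
#'   (list of shape descriptors), `noise_fraction` (0 for a freshly
#'   generated scene) and `seed`.
#' @section Errors: `retry_exhausted_error` when 100 redraws fail to
#'   produce a curve with at least 10 in-frame pixels.
#' @export
generate_scene <- function(height = 512L, width = 512L,
                           n_lines = 3L, n_circles = 2L,
                           coeff_ranges = list(
                             abs_A = c(1 / 200, 1 / 40),
                             vertex_t = c(0.25, 0.75),
                             vertex_s = c(0.2, 0.8)),
                           min_pixels = 100L, max_pixels = 500L,
                           thickness = 3L, seed = NULL) {
  stopifnot(height >= 1, width >= 1, n_lines >= 0, n_circles >= 0,
            all(coeff_ranges$abs_A > 0), thickness >= 0)
  if (!is.null(seed)) set.seed(seed)

  truth <- NULL
  best_draw <- NULL; best_count <- -1L
  for (attempt in 1:100) {
    A <- sample(c(-1, 1), 1L) * stats::runif(1, coeff_ranges$abs_A[1],
                                             coeff_ranges$abs_A[2])
    tv <- stats::runif(1, coeff_ranges$vertex_t[1] * height,
                       coeff_ranges$vertex_t[2] * height)
    sv <- stats::runif(1, coeff_ranges$vertex_s[1] * width,
                       coeff_ranges$vertex_s[2] * width)
    B <- -2 * A * tv
    C <- sv + B^2 / (4 * A)
    cand <- parabola(A, B, C)
    cnt <- rasterize(cand, height, width)$N
    if (cnt > best_count) { best_count <- cnt; best_draw <- cand }
    if (cnt >= min_pixels && cnt <= max_pixels) { truth <- cand; break }
  }
  if (is.null(truth)) {
    if (best_count >= 10L) {
      truth <- best_draw
    } else {
      stop(retry_exhausted_error(
        "could not draw a parabola with at least 10 in-frame pixels in 100 attempts"))
    }
  }
  grid <- rasterize(truth, height, width)$grid
  distractors <- list()

  # distractor segments: random position and orientation, length bounded
  # so no single line can out-score the planted curve's raster
  for (i in seq_len(n_lines)) {
    x0 <- stats::runif(1, 0, width - 1)
    y0 <- stats::runif(1, 0, height - 1)
    ang <- stats::runif(1, 0, pi)
    len <- stats::runif(1, min(height, width) / 8, min(height, width) / 3)
    ends <- round_half_away(c(x0, y0, x0 + len * cos(ang),
                              y0 + len * sin(ang)))
    grid <- draw_line(grid, ends[1], ends[2], ends[3], ends[4])
    distractors[[length(distractors) + 1L]] <-
      list(type = "line", x0 = ends[1], y0 = ends[2],
           x1 = ends[3], y1 = ends[4])
  }
  for (i in seq_len(n_circles)) {
    cx <- sample.int(width, 1L) - 1L
    cy <- sample.int(height, 1L) - 1L
    r <- sample(seq(round(min(height, width) / 16),
                    round(min(height, width) / 5)), 1L)
    grid <- draw_circle(grid, cx, cy, r)
    distractors[[length(distractors) + 1L]] <-
      list(type = "circle", cx = cx, cy = cy, r = r)
  }

  if (thickness > 0L) grid <- dilate_grid(grid, as.integer(thickness))

  structure(list(image = edge_image(grid), truth = truth,
                 distractors = distractors, noise_fraction = 0,
                 thickness = as.integer(thickness), seed = seed),
            class = "synthetic_scene")
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf("synthetic_scene: %d x %d, N = %d, %d distractor(s), noise %.0f%%\n",
              nrow(x$image$grid), ncol(x$image$grid), x$image$N,
              length(x$distractors), 100 * x$noise_fraction))
  invisible(x)
}

# integer line rasterization by stepping along the dominant axis
draw_line <- function(grid, x0, y0, x1, y1) {
  steps <- max(abs(x1 - x0), abs(y1 - y0))
  if (steps == 0) {
    if (y0 >= 0 && y0 < nrow(grid) && x0 >= 0 && x0 < ncol(grid)) {
      grid[y0 + 1L, x0 + 1L] <- 1L
    }
    return(grid)
  }
  t <- 0:steps
  xs <- round_half_away(x0 + t * (x1 - x0) / steps)
  ys <- round_half_away(y0 + t * (y1 - y0) / steps)
  ok <- xs >= 0 & xs < ncol(grid) & ys >= 0 & ys < nrow(grid)
  grid[cbind(ys[ok] + 1L, xs[ok] + 1L)] <- 1L
  grid
}

# midpoint circle algorithm; out-of-frame arc pixels are clipped
draw_circle <- function(grid, cx, cy, r) {
  x <- r; y <- 0L; err <- 1L - r
  pts <- matrix(integer(0), ncol = 2)
  while (x >= y) {
    pts <- rbind(pts,
                 c(cx + x, cy + y), c(cx - x, cy + y),
                 c(cx + x, cy - y), c(cx - x, cy - y),
                 c(cx + y, cy + x), c(cx - y, cy + x),
                 c(cx + y, cy - x), c(cx - y, cy - x))
    y <- y + 1L
    if (err < 0L) {
      err <- err + 2L * y + 1L
    } else {
      x <- x - 1L
      err <- err + 2L * (y - x) + 1L
    }
  }
  ok <- pts[, 1] >= 0 & pts[, 1] < ncol(grid) &
        pts[, 2] >= 0 & pts[, 2] < nrow(grid)
  grid[cbind(pts[ok, 2] + 1L, pts[ok, 1] + 1L)] <- 1L
  grid
}

#' Add salt-and-pepper noise to a binary image
#'
#' Selects exactly `round(fraction * height * width)` distinct pixel
#' sites uniformly at random (without replacement) and resamples each to
#' foreground ("salt") with probability 1/2, otherwise background
#' ("pepper"); unselected pixels are untouched.  On a binary edge image
#' the grayscale extremes coincide with the two binary values, so
#' impulse noise reduces to this site resampling.
#'
#' @param img An [edge_image()] or binary matrix.
#' @param fraction Fraction of sites to corrupt, in `[0, 1]`.
#' @param seed Optional integer seed.
#' @return A new [edge_image()].
#' @export
add_salt_pepper <- function(img, fraction, seed = NULL) {
  img <- as_edge_image(img)
  stopifnot(fraction >= 0, fraction <= 1)
  if (!is.null(seed)) set.seed(seed)
  grid <- img$grid
  n_sites <- round(fraction * length(grid))
  if (n_sites > 0) {
    sites <- sample.int(length(grid), n_sites)
    grid[sites] <- as.integer(stats::runif(n_sites) < 0.5)
  }
  edge_image(grid)
}

#' Skeletonize a binary image by Zhang-Suen thinning
#'
#' Iteratively peels boundary pixels in the standard two-subiteration
#' scheme until stability, reducing connected shapes to one-pixel-wide
#' medial curves while preserving connectivity and endpoints.
#'
#' @param img An [edge_image()] or binary matrix.
#' @return A thinned [edge_image()].
#' @export
skeletonize <- function(img) {
  img <- as_edge_image(img)
  m <- img$grid == 1L
  nr <- nrow(m); nc <- ncol(m)
  pad <- function(x) {
    p <- matrix(FALSE, nr + 2L, nc + 2L)
    p[2:(nr + 1L), 2:(nc + 1L)] <- x
    p
  }
  repeat {
    changed <- FALSE
    for (step in 0:1) {
      p <- pad(m)
      nb <- function(dr, dc) p[(2L + dr):(nr + 1L + dr), (2L + dc):(nc + 1L + dc)]
      p2 <- nb(-1L, 0L); p3 <- nb(-1L, 1L); p4 <- nb(0L, 1L)
      p5 <- nb(1L, 1L);  p6 <- nb(1L, 0L);  p7 <- nb(1L, -1L)
      p8 <- nb(0L, -1L); p9 <- nb(-1L, -1L)
      bsum <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      ring <- list(p2, p3, p4, p5, p6, p7, p8, p9, p2)
      a01 <- Reduce(`+`, lapply(1:8, function(i) (!ring[[i]]) & ring[[i + 1L]]))
      del <- m & bsum >= 2 & bsum <= 6 & a01 == 1
      if (step == 0L) {
        del <- del & !(p2 & p4 & p6) & !(p4 & p6 & p8)
      } else {
        del <- del & !(p2 & p4 & p8) & !(p2 & p6 & p8)
      }
      if (any(del)) { m[del] <- FALSE; changed <- TRUE }
    }
    if (!changed) break
  }
  edge_image(matrix(as.integer(m), nr, nc))
}

#' Build the noise-sweep scene battery
#'
#' The full evaluation battery: `n_base` independently drawn base scenes
#' crossed with every integer salt-and-pepper noise percentage in
#' `noise_levels`, the planted truth carried over unchanged.  The
#' defaults (10 base scenes, levels 0-25 percent) yield 260 test scenes.
#'
#' @param n_base Number of base scenes (default 10).
#' @param noise_levels Integer noise percentages (default `0:25`).
#' @param height,width Frame size passed to [generate_scene()].
#' @param n_lines,n_circles Distractor counts per base scene.
#' @param seed Master seed; per-scene seeds are derived from it
#'   deterministically.
#' @return A list of `"synthetic_scene"` objects of length
#'   `n_base * length(noise_levels)`, each with its `noise_fraction` set
#'   and a `base_id` field identifying the parent scene.
#' @export
build_noise_battery <- function(n_base = 10L, noise_levels = 0:25,
                                height = 512L, width = 512L,
                                n_lines = 3L, n_circles = 2L,
                                seed = NULL) {
  stopifnot(n_base >= 1, all(noise_levels >= 0), all(noise_levels <= 100))
  if (!is.null(seed)) set.seed(seed)
  seeds <- sample.int(.Machine$integer.max,
                      n_base * (1L + length(noise_levels)))
  out <- vector("list", n_base * length(noise_levels))
  k <- 0L
  for (b in seq_len(n_base)) {
    base <- generate_scene(height = height, width = width,
                           n_lines = n_lines, n_circles = n_circles,
                           seed = seeds[b])
    for (li in seq_along(noise_levels)) {
      lev <- noise_levels[li]
      sc <- base
      if (lev > 0) {
        sc$image <- add_salt_pepper(base$image, lev / 100,
                                    seed = seeds[n_base + (b - 1L) *
                                                   length(noise_levels) + li])
      }
      sc$noise_fraction <- lev / 100
      sc$base_id <- b
      k <- k + 1L
      out[[k]] <- sc
    }
  }
  out
}
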