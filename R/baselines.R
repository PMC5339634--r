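#' Discretized parameter grid for the parabola Hough transform
#'
#' The accumulator axes for the vertex form `(y - y0)^2 = 4a (x - x0)`:
#' candidate vertex columns `x0`, vertex rows `y0`, and apertures `a`
#' (all in pixels; `a` must exclude 0).
#'
#' @param x0_values,y0_values,a_values Numeric axes; `a_values` must be
#'   non-zero.
#' @return A list of class `"hough_grid"`.
#' @export
hough_grid <- function(x0_values, y0_values, a_values) {
  stopifnot(length(x0_values) >= 1, length(y0_values) >= 1,
            length(a_values) >= 1, all(a_values != 0))
  structure(list(x0_values = as.numeric(x0_values),
                 y0_values = as.numeric(y0_values),
                 a_values = as.numeric(a_values)),
            class = "hough_grid")
}

#' A default Hough grid spanning an image frame
#'
#' Vertex axes cover the frame at the given resolution; apertures span
#' both opening directions over a magnitude range wide enough for curves
#' whose in-frame span is a substantial part of the frame.
#'
#' @param height,width Frame size in pixels.
#' @param n_x0,n_y0,n_a Number of grid nodes per axis.
#' @param a_range Magnitude range of the aperture parameter `a`.
#' @return A [hough_grid()].
#' @export
default_hough_grid <- function(height, width, n_x0 = 32L, n_y0 = 32L,
                               n_a = 16L, a_range = c(5, width / 2)) {
  amag <- seq(a_range[1], a_range[2], length.out = max(1L, n_a %/% 2L))
  hough_grid(seq(0, width - 1, length.out = n_x0),
             seq(0, height - 1, length.out = n_y0),
             c(-rev(amag), amag))
}

#' Parabola detection by Hough-transform voting
#'
#' Every foreground pixel `(x, y)` votes: for each accumulator cell
#' `(a, y0)` the remaining parameter is solved from the vertex form,
#' `x0 = x - (y - y0)^2 / (4a)`, binned to the nearest `x0` axis node,
#' and the vote recorded.  The detected parabola is read off the
#' accumulator argmax (lowest linear index on ties) and converted to the
#' general form `x = A y^2 + B y + C` with `A = 1/(4a)`,
#' `B = -y0/(2a)`, `C = y0^2/(4a) + x0`.
#'
#' @param img An [edge_image()] or binary matrix.
#' @param grid A [hough_grid()].
#' @return A list with `parabola`, `votes` (the winning cell's count),
#'   `accumulator` (3D array `|x0| x |y0| x |a|`) and the grid.
#' @export
detect_parabola_hough <- function(img, grid) {
  img <- as_edge_image(img)
  stopifnot(inherits(grid, "hough_grid"))
  x0v <- grid$x0_values; y0v <- grid$y0_values; av <- grid$a_values
  acc <- array(0L, dim = c(length(x0v), length(y0v), length(av)))
  if (img$N > 0L) {
    px <- img$foreground[, "x"]; py <- img$foreground[, "y"]
    # bin edges halfway between x0 nodes (left-open: a midpoint tie goes
    # to the lower-index node); votes outside the axis are dropped
    brk <- c(-Inf, (x0v[-1] + x0v[-length(x0v)]) / 2, Inf)
    for (ia in seq_along(av)) {
      for (iy in seq_along(y0v)) {
        x0 <- px - (py - y0v[iy])^2 / (4 * av[ia])
        ix <- findInterval(x0, brk, left.open = TRUE)
        # reject votes farther than one full axis spacing from the node
        near <- abs(x0 - x0v[ix]) <= axis_halfwidth(x0v, ix)
        counts <- tabulate(ix[near], nbins = length(x0v))
        acc[, iy, ia] <- acc[, iy, ia] + counts
      }
    }
  }
  peak <- which.max(acc)  # first max = lowest linear index on ties
  pk <- arrayInd(peak, dim(acc))
  x0 <- x0v[pk[1]]; y0 <- y0v[pk[2]]; a <- av[pk[3]]
  p <- parabola(1 / (4 * a), -y0 / (2 * a), y0^2 / (4 * a) + x0)
  list(parabola = p, votes = acc[peak], accumulator = acc, grid = grid)
}

# half-width of the binning window around each axis node: half the larger
# adjacent spacing (a single-node axis accepts everything)
axis_halfwidth <- function(axis, idx) {
  n <- length(axis)
  if (n == 1L) return(rep(Inf, length(idx)))
  sp <- diff(axis)
  hw <- if (n == 2L) c(sp, sp) / 2
        else c(sp[1], pmax(sp[-(n - 1L)], sp[-1L]), sp[n - 1L]) / 2
  hw[idx]
}

#' Export a Hough accumulator for inspection
#'
#' Writes the flattened vote array as CSV (`x0, y0, a, votes` rows for
#' non-zero cells) plus a JSON sidecar with the axis values.
#'
#' @param hough Result of [detect_parabola_hough()].
#' @param path Output CSV path; the sidecar is `paste0(path, ".axes.json")`.
#' @return Invisibly, the data frame written.
#' @export
write_accumulator <- function(hough, path) {
  acc <- hough$accumulator
  nz <- which(acc > 0L)
  idx <- arrayInd(nz, dim(acc))
  df <- data.frame(x0 = hough$grid$x0_values[idx[, 1]],
                   y0 = hough$grid$y0_values[idx[, 2]],
                   a = hough$grid$a_values[idx[, 3]],
                   votes = acc[nz])
  utils::write.csv(df, path, row.names = FALSE)
  writeLines(jsonlite::toJSON(hough$grid[], auto_unbox = FALSE, digits = NA),
             paste0(path, ".axes.json"))
  invisible(df)
}

#' RANSAC parameters
#'
#' @param iterations Number of minimal-sample trials (default 5000, the
#'   iteration count reported for the RANSAC comparison).
#' @param inlier_tolerance Per-row horizontal residual bound in pixels
#'   (default 2, matched to 3-px-thick dilated edges).
#' @param seed Optional integer seed.
#' @return A list of class `"ransac_params"`.
#' @export
ransac_params <- function(iterations = 5000L, inlier_tolerance = 2.0,
                          seed = NULL) {
  stopifnot(iterations >= 1, inlier_tolerance > 0)
  structure(list(iterations = as.integer(iterations),
                 inlier_tolerance = inlier_tolerance, seed = seed),
            class = "ransac_params")
}

#' Parabola detection by RANSAC
#'
#' Repeats `iterations` times: draw three distinct foreground pixels,
#' fit the interpolating parabola (degenerate triplets are skipped), and
#' count inliers -- foreground pixels whose horizontal residual
#' `|x - (A y^2 + B y + C)|` is at most the tolerance.  The best model
#' is refit by least squares on its inliers via the quadratic normal
#' equations, and inliers are recounted against the refit model.
#'
#' @param img An [edge_image()] or binary matrix with `N >= 3`.
#' @param params A [ransac_params()].
#' @return A `"detection_result"` whose `fitness` is the inlier count of
#'   the returned model and whose `evaluations` equals `iterations`.
#' @section Errors: `empty_image_error` when `N < 3`.
#' @export
detect_parabola_ransac <- function(img, params = ransac_params()) {
  img <- as_edge_image(img)
  stopifnot(inherits(params, "ransac_params"))
  if (img$N < 3L) {
    stop(empty_image_error(sprintf(
      "edge image has %d foreground pixel(s); at least 3 are required",
      img$N)))
  }
  if (!is.null(params$seed)) set.seed(params$seed)
  t0 <- proc.time()[["elapsed"]]
  px <- img$foreground[, "x"]; py <- img$foreground[, "y"]
  tol <- params$inlier_tolerance

  best <- NULL; best_inliers <- -1L; best_idx <- NULL
  for (it in seq_len(params$iterations)) {
    s <- sample.int(img$N, 3L)
    p <- tryCatch(
      fit_three_points(c(px[s[1]], py[s[1]]), c(px[s[2]], py[s[2]]),
                       c(px[s[3]], py[s[3]])),
      degenerate_triplet_error = function(e) NULL)
    if (is.null(p)) next
    r <- abs(px - (p$A * py * py + p$B * py + p$C))
    k <- sum(r <= tol)
    if (k > best_inliers) {
      best_inliers <- k
      best <- p
      best_idx <- s
    }
  }
  if (is.null(best)) {
    stop(degenerate_triplet_error(
      "every sampled triplet was degenerate; cannot fit a parabola"))
  }

  # least-squares refit on the winning model's inliers (normal equations);
  # the refit is kept only when it does not lose consensus
  r <- abs(px - (best$A * py * py + best$B * py + best$C))
  inl <- which(r <= tol)
  refit <- tryCatch(ls_refit(px[inl], py[inl]), error = function(e) NULL)
  final <- best
  final_inliers <- best_inliers
  if (!is.null(refit)) {
    rf <- abs(px - (refit$A * py * py + refit$B * py + refit$C))
    if (sum(rf <= tol) >= best_inliers) {
      final <- refit
      final_inliers <- sum(rf <= tol)
    }
  }

  structure(list(parabola = final,
                 indices = as.integer(best_idx - 1L),
                 fitness = as.integer(final_inliers),
                 generations = params$iterations,
                 best_generation = NA_integer_,
                 evaluations = params$iterations,
                 history = NULL,
                 method = "ransac",
                 elapsed = proc.time()[["elapsed"]] - t0),
            class = "detection_result")
}

# solve min ||X beta - x||^2 with X = [y^2, y, 1] via the normal equations
ls_refit <- function(x, y) {
  X <- cbind(y * y, y, 1)
  beta <- solve(crossprod(X), crossprod(X, x))
  parabola(beta[1], beta[2], beta[3])
}
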