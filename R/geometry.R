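#' Parabola in general form
#'
#' Constructs a parabola described by its general form
#' \eqn{A t^2 + B t + C = s}, where `t` is the quadratic argument and `s`
#' the dependent coordinate.  With the canonical orientation `"x_of_y"`
#' the curve is sideways: `x = A y^2 + B y + C` (x = column, y = row,
#' 0-based, origin at the top-left).  Orientation `"y_of_x"` denotes the
#' upright curve `y = A x^2 + B x + C`, handled everywhere by logical
#' transposition of the image.
#'
#' @param A Quadratic coefficient (1/pixels).  Must satisfy
#'   `abs(A) >= 1e-12`; smaller magnitudes describe a line, not a
#'   parabola, and are rejected.
#' @param B Linear coefficient (dimensionless).
#' @param C Constant term (pixels).
#' @param orientation `"x_of_y"` (default, sideways) or `"y_of_x"`.
#' @return An object of class `"parabola"`.
#' @examples
#' p <- parabola(1, 0, 0)   # x = y^2
#' parabola_eval(p, 3)      # 9
#' @export
parabola <- function(A, B, C, orientation = c("x_of_y", "y_of_x")) {
  orientation <- match.arg(orientation)
  stopifnot(is.numeric(A), is.numeric(B), is.numeric(C),
            length(A) == 1L, length(B) == 1L, length(C) == 1L,
            is.finite(A), is.finite(B), is.finite(C))
  if (abs(A) < 1e-12) {
    stop(degenerate_triplet_error(
      "quadratic coefficient A is (numerically) zero: the curve is a line"))
  }
  structure(list(A = as.numeric(A), B = as.numeric(B), C = as.numeric(C),
                 orientation = orientation),
            class = "parabola")
}

#' @export
print.parabola <- function(x, ...) {
  va <- vertex_aperture(x)
  eqn <- if (x$orientation == "x_of_y") "x = A*y^2 + B*y + C"
         else "y = A*x^2 + B*x + C"
  cat(sprintf("parabola (%s): A=%.6g  B=%.6g  C=%.6g\n",
              eqn, x$A, x$B, x$C))
  cat(sprintf("  vertex (x=%.4g, y=%.4g)  aperture 4p=%.6g\n",
              va$vertex_x, va$vertex_y, va$four_p))
  invisible(x)
}

# condition constructors -----------------------------------------------------

degenerate_triplet_error <- function(msg) {
  errorCondition(msg, class = c("degenerate_triplet_error", "parabolaEDA_error"))
}

empty_image_error <- function(msg) {
  errorCondition(msg, class = c("empty_image_error", "parabolaEDA_error"))
}

retry_exhausted_error <- function(msg) {
  errorCondition(msg, class = c("retry_exhausted_error", "parabolaEDA_error"))
}

# round half away from zero (symmetric, locale-independent; base round()
# rounds half to even, which would bias rasterization at .5 columns)
round_half_away <- function(v) trunc(v + 0.5 * sign(v))

#' Fit the unique parabola through three pixels
#'
#' Computes the closed-form coefficients of the interpolating quadratic
#' `x = A y^2 + B y + C` through three points with pairwise distinct
#' quadratic-argument coordinates:
#' \deqn{A = \frac{y_k(x_j-x_i) + y_j(x_i-x_k) + y_i(x_k-x_j)}
#'            {(y_i-y_j)(y_i-y_k)(y_j-y_k)}}
#' and analogous closed forms for B and C.  The three points are the
#' decoded pixels of one optimizer individual.
#'
#' @param p1,p2,p3 Numeric vectors `c(x, y)` in pixel coordinates
#'   (x = column, y = row, 0-based).
#' @return A [parabola()] passing exactly through the three points.
#' @section Errors: signals a `degenerate_triplet_error` when two
#'   quadratic-argument coordinates coincide (the closed-form denominator
#'   vanishes) or when the interpolant is a line (`|A| < 1e-12`).
#' @examples
#' fit_three_points(c(0, 0), c(1, 1), c(4, 2))  # x = y^2
#' @export
fit_three_points <- function(p1, p2, p3) {
  xi <- as.numeric(p1[[1]]); yi <- as.numeric(p1[[2]])
  xj <- as.numeric(p2[[1]]); yj <- as.numeric(p2[[2]])
  xk <- as.numeric(p3[[1]]); yk <- as.numeric(p3[[2]])
  den <- (yi - yj) * (yi - yk) * (yj - yk)
  if (den == 0) {
    stop(degenerate_triplet_error(
      "two of the three pixels share the same quadratic-argument coordinate"))
  }
  # Newton divided-difference evaluation of the closed form: algebraically
  # identical to the direct ratio-of-products expressions but much better
  # conditioned at image-scale coordinates
  d1 <- (xj - xi) / (yj - yi)
  d2 <- ((xk - xj) / (yk - yj) - d1) / (yk - yi)
  A <- d2
  B <- d1 - d2 * (yi + yj)
  C <- xi - yi * d1 + yi * yj * d2
  if (abs(A) < 1e-12) {
    stop(degenerate_triplet_error(
      "the three pixels are collinear in the fitted frame (A = 0)"))
  }
  parabola(A, B, C)
}

#' Vertex and aperture of a parabola
#'
#' For the sideways form `x = A y^2 + B y + C`, completing the square
#' gives the vertex at `y = -B/(2A)`, `x = C - B^2/(4A)` and the aperture
#' (latus rectum) `4p = 1/A`.  The sign of `4p` gives the opening
#' direction and its magnitude the opening width.  For orientation
#' `"y_of_x"` the roles of x and y swap.
#'
#' @param p A [parabola()].
#' @return A list with `vertex_x`, `vertex_y`, `four_p`.
#' @examples
#' vertex_aperture(parabola(1, -4, 5))  # vertex y = 2, x = 1, 4p = 1
#' @export
vertex_aperture <- function(p) {
  stopifnot(inherits(p, "parabola"))
  t_v <- -p$B / (2 * p$A)          # quadratic-argument coordinate
  s_v <- p$C - p$B^2 / (4 * p$A)   # dependent coordinate
  if (p$orientation == "x_of_y") {
    list(vertex_x = s_v, vertex_y = t_v, four_p = 1 / p$A)
  } else {
    list(vertex_x = t_v, vertex_y = s_v, four_p = 1 / p$A)
  }
}

#' Evaluate a parabola at given quadratic arguments
#'
#' Returns `A*t^2 + B*t + C`.  For the canonical `"x_of_y"` orientation
#' `t` is a row coordinate and the result a column coordinate.
#'
#' @param p A [parabola()].
#' @param t Numeric vector of quadratic-argument coordinates.
#' @return Numeric vector of dependent coordinates.
#' @export
parabola_eval <- function(p, t) {
  stopifnot(inherits(p, "parabola"))
  p$A * t * t + p$B * t + p$C
}

#' Rasterize a parabola into a virtual-shape edge image
#'
#' Produces the virtual shape I_VS used by the Hadamard fitness: for each
#' integer quadratic argument `t` along its axis the dependent coordinate
#' is rounded (half away from zero) and the corresponding pixel set to 1
#' when it falls inside the frame.  At most one pixel is emitted per row
#' (per column for `"y_of_x"`); a curve entirely out of frame yields an
#' all-zero image.
#'
#' @param p A [parabola()].
#' @param height,width Frame dimensions in pixels (both > 0).
#' @param thickness Optional dilation radius (pixels) applied to the
#'   raster with a Euclidean disk structuring element; default 0 keeps
#'   the 1-pixel-per-row curve used by the fitness function.
#' @return An [edge_image()] of the requested size.
#' @export
rasterize <- function(p, height, width, thickness = 0L) {
  stopifnot(inherits(p, "parabola"),
            length(height) == 1L, length(width) == 1L,
            height >= 1, width >= 1, thickness >= 0)
  grid <- matrix(0L, nrow = height, ncol = width)
  if (p$orientation == "x_of_y") {
    t <- 0:(height - 1L)
    x <- round_half_away(parabola_eval(p, t))
    ok <- is.finite(x) & x >= 0 & x < width
    if (any(ok)) grid[cbind(t[ok] + 1L, x[ok] + 1L)] <- 1L
  } else {
    t <- 0:(width - 1L)
    y <- round_half_away(parabola_eval(p, t))
    ok <- is.finite(y) & y >= 0 & y < height
    if (any(ok)) grid[cbind(y[ok] + 1L, t[ok] + 1L)] <- 1L
  }
  if (thickness > 0L) grid <- dilate_grid(grid, as.integer(thickness))
  edge_image(grid)
}

#' Serialize a parabola to JSON
#'
#' Emits a JSON object with the general-form coefficients, orientation,
#' vertex coordinates and aperture.
#'
#' @param p A [parabola()].
#' @param path Optional file path; when `NULL` the JSON string is
#'   returned.
#' @return A JSON string (invisibly when written to `path`).
#' @export
parabola_json <- function(p, path = NULL) {
  stopifnot(inherits(p, "parabola"))
  va <- vertex_aperture(p)
  obj <- list(A = p$A, B = p$B, C = p$C, orientation = p$orientation,
              vertex_x = va$vertex_x, vertex_y = va$vertex_y,
              four_p = va$four_p)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
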