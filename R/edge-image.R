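#' Binary edge image with indexed foreground pixels
#'
#' The search space of the detectors: a binary grid together with the
#' ordered list of its foreground pixels.  Pixels are listed in row-major
#' scan order (top row left to right, then the next row) and labelled
#' with 0-based indices `0..N-1`; the optimizer's individuals address
#' pixels through these indices.
#'
#' @param grid Numeric or integer matrix; any non-zero entry is
#'   foreground.  Rows are y (0-based from the top), columns are x.
#' @return An object of class `"edge_image"`: a list with `grid`
#'   (0/1 integer matrix), `foreground` (N x 2 integer matrix with
#'   columns `x`, `y`, 0-based, row-major order) and `N`.
#' @examples
#' g <- diag(3)
#' img <- edge_image(g)
#' img$N            # 3
#' img$foreground   # (0,0), (1,1), (2,2)
#' @export
edge_image <- function(grid) {
  stopifnot(is.matrix(grid), nrow(grid) >= 1, ncol(grid) >= 1)
  g <- matrix(as.integer(grid != 0), nrow = nrow(grid))
  hits <- which(g == 1L, arr.ind = TRUE)
  ord <- order(hits[, 1L], hits[, 2L])  # row-major: by row, then column
  fg <- cbind(x = hits[ord, 2L] - 1L, y = hits[ord, 1L] - 1L)
  structure(list(grid = g, foreground = fg, N = nrow(fg)),
            class = "edge_image")
}

#' Index the foreground pixels of a binary grid
#'
#' Same construction as [edge_image()], but additionally requires at
#' least three foreground pixels so that a triplet individual can be
#' formed; this is the entry point the detectors use on user-supplied
#' edge maps.
#'
#' @inheritParams edge_image
#' @return An `"edge_image"` with `N >= 3`.
#' @section Errors: signals an `empty_image_error` when fewer than three
#'   foreground pixels are present.
#' @export
index_pixels <- function(grid) {
  img <- edge_image(grid)
  if (img$N < 3L) {
    stop(empty_image_error(sprintf(
      "edge image has %d foreground pixel(s); at least 3 are required", img$N)))
  }
  img
}

#' @export
print.edge_image <- function(x, ...) {
  cat(sprintf("edge_image: %d x %d, N = %d foreground pixels\n",
              nrow(x$grid), ncol(x$grid), x$N))
  invisible(x)
}

# transpose an edge image (x <-> y), used for the y_of_x orientation
transpose_edge_image <- function(img) edge_image(t(img$grid))

as_edge_image <- function(x) {
  if (inherits(x, "edge_image")) x else edge_image(x)
}
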