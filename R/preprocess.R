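#' Smooth a grayscale image with a 3x3 mean filter
#'
#' Convolves the image with the 3x3 kernel of all 1/9 entries, the first
#' stage of the edge-image conditioning chain; it suppresses isolated
#' spurious pixels before gradient computation.  Borders use replicate
#' padding, so a constant image is a fixed point and the output range
#' never exceeds the input range.
#'
#' @param img Numeric matrix of intensities (any affine range, e.g.
#'   `[0, 1]` or `[0, 255]`).
#' @return Numeric matrix of the same size.
#' @export
mean_filter <- function(img) {
  stopifnot(is.matrix(img), all(is.finite(img)))
  k <- matrix(1 / 9, 3, 3)
  as.matrix(EBImage::filter2(img, k, boundary = "replicate"))
}

#' Canny edge detection
#'
#' Sobel gradients on the (already smoothed) image, non-maximum
#' suppression along the quantized gradient direction, and hysteresis
#' thresholding: weak edge pixels survive only in connected components
#' that contain at least one strong pixel.  Thresholds apply to the
#' gradient magnitude; when omitted, `high` defaults to the Otsu
#' threshold of the magnitude map and `low` to `high / 2`.
#'
#' @param img Numeric intensity matrix.
#' @param low,high Hysteresis thresholds on gradient magnitude
#'   (`low < high`); `NULL` selects the Otsu-scaled defaults.
#' @return An [edge_image()] of thin (non-maximum-suppressed) edges.
#' @export
canny_edges <- function(img, low = NULL, high = NULL) {
  stopifnot(is.matrix(img), all(is.finite(img)))
  sx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3, byrow = TRUE)
  sy <- t(sx)
  gx <- as.matrix(EBImage::filter2(img, sx, boundary = "replicate"))
  gy <- as.matrix(EBImage::filter2(img, sy, boundary = "replicate"))
  mag <- sqrt(gx^2 + gy^2)
  mmax <- max(mag)
  # guard against FFT round-off on flat images masquerading as gradients
  if (mmax <= 1e-8 * max(1, max(abs(img)))) {
    return(edge_image(matrix(0L, nrow(img), ncol(img))))
  }

  if (is.null(high)) {
    high <- tryCatch(
      EBImage::otsu(EBImage::Image(mag / mmax), range = c(0, 1)) * mmax,
      error = function(e) 0.2 * mmax)
  }
  if (is.null(low)) low <- high / 2
  stopifnot(low < high)

  # non-maximum suppression: compare with the two neighbors along the
  # gradient direction quantized to {0, 45, 90, 135} degrees
  ang <- atan2(gy, gx)
  ang[ang < 0] <- ang[ang < 0] + pi
  sector <- (round_half_away(ang / (pi / 4)) %% 4)  # 0:E-W 1:NE-SW 2:N-S 3:NW-SE
  nr <- nrow(img); nc <- ncol(img)
  padm <- matrix(-Inf, nr + 2L, nc + 2L)
  padm[2:(nr + 1L), 2:(nc + 1L)] <- mag
  shift <- function(dr, dc) padm[(2L + dr):(nr + 1L + dr), (2L + dc):(nc + 1L + dc)]
  # gradient direction (dy, dx) per sector: 0 -> horizontal gradient (E/W
  # neighbors), 1 -> diagonal, 2 -> vertical, 3 -> anti-diagonal
  n1 <- shift(0L, 1L);  n1b <- shift(0L, -1L)
  n2 <- shift(-1L, 1L); n2b <- shift(1L, -1L)
  n3 <- shift(-1L, 0L); n3b <- shift(1L, 0L)
  n4 <- shift(-1L, -1L); n4b <- shift(1L, 1L)
  keep <- (sector == 0 & mag >= n1 & mag >= n1b) |
          (sector == 1 & mag >= n2 & mag >= n2b) |
          (sector == 2 & mag >= n3 & mag >= n3b) |
          (sector == 3 & mag >= n4 & mag >= n4b)
  thin <- mag * keep

  strong <- thin >= high
  weak <- thin >= low
  if (!any(strong)) return(edge_image(matrix(0L, nr, nc)))
  lab <- EBImage::bwlabel(EBImage::Image(weak * 1))
  lab <- as.matrix(EBImage::imageData(lab))
  keep_labels <- unique(lab[strong])
  edges <- weak & (lab %in% keep_labels)
  edge_image(matrix(as.integer(edges), nr, nc))
}

# Euclidean disk structuring element: pixels with center distance <= radius
disk_kernel <- function(radius) {
  r <- as.integer(radius)
  d <- 2L * r + 1L
  off <- matrix(rep(-r:r, d), d, d)
  matrix(as.numeric(off^2 + t(off)^2 <= r^2), d, d)
}

# morphological dilation of a 0/1 integer matrix with a disk SE
dilate_grid <- function(grid, radius) {
  if (sum(grid) == 0L) return(grid)
  out <- EBImage::dilate(EBImage::Image(grid), disk_kernel(radius))
  matrix(as.integer(as.matrix(EBImage::imageData(out)) > 0),
         nrow(grid), ncol(grid))
}

#' Dilate a binary edge image with a disk structuring element
#'
#' The final conditioning stage, `f_binary = f_edge (+) SE`: dilation
#' with a Euclidean disk closes slightly open contours and thickens
#' borders so the 1-pixel-per-row candidate rasters can match them.
#' The default radius is 3.
#'
#' @param img An [edge_image()] or binary matrix.
#' @param radius Disk radius in pixels (>= 1, default 3); a pixel belongs
#'   to the SE when its center distance is at most `radius`.
#' @return A dilated [edge_image()]; the output foreground is a superset
#'   of the input foreground.
#' @export
dilate_edges <- function(img, radius = 3L) {
  img <- as_edge_image(img)
  stopifnot(radius >= 1)
  edge_image(dilate_grid(img$grid, as.integer(radius)))
}

#' Split a foot image into fingers / arch / heel bands
#'
#' Divides the image into three horizontal bands of (as near as
#' possible) one third of the rows each, along the fingers-to-heel axis;
#' the middle band contains the plantar arch and the bottom band the
#' heel, the two regions of diagnostic interest.  When the height is not
#' divisible by 3 the remainder rows go to the top (fingers) band, so
#' band heights differ by at most one row and always recompose the full
#' image.
#'
#' @param img Numeric matrix (grayscale or binary), `height >= 3`.
#' @param flip Set `TRUE` when the fingers are at the bottom of the
#'   frame; the image is flipped vertically before sectioning.
#' @return A list of class `"foot_sections"` with elements `fingers`,
#'   `arch`, `heel`, each a list of `pixels` (the band submatrix) and
#'   `row_offset` (0-based first row in the full frame), plus `flipped`.
#' @export
section_foot <- function(img, flip = FALSE) {
  stopifnot(is.matrix(img), nrow(img) >= 3)
  if (flip) img <- img[rev(seq_len(nrow(img))), , drop = FALSE]
  h <- nrow(img)
  base <- h %/% 3L
  heights <- c(base + h %% 3L, base, base)
  offs <- cumsum(c(0L, heights[-3L]))
  band <- function(i) list(
    pixels = img[(offs[i] + 1L):(offs[i] + heights[i]), , drop = FALSE],
    row_offset = offs[i])
  structure(list(fingers = band(1L), arch = band(2L), heel = band(3L),
                 flipped = flip),
            class = "foot_sections")
}

#' Detect the plantar-arch and heel parabolas in a foot image
#'
#' Runs the full conditioning chain (mean filter, Canny edges, disk
#' dilation), splits the binary result into thirds, and detects one
#' parabola per region of interest (arch = middle band, heel = bottom
#' band) with the UMDA.  Both contours bend around a vertical axis, so
#' detection uses the upright `y = A x^2 + B x + C` orientation
#' (internally a transposed sideways detection); detected vertices are
#' mapped back to full-image coordinates.
#'
#' @param img Numeric grayscale matrix.
#' @param params An [umda_params()].
#' @param radius Dilation radius (default 3).
#' @param low,high Optional Canny thresholds (default Otsu-scaled).
#' @param flip Fingers at the bottom of the frame.
#' @param keep_stages Return the intermediate smooth/edge/binary images.
#' @return A list with `arch` and `heel` detection results (each with a
#'   `row_offset` field and a `vertex` mapped to full-image
#'   coordinates), plus the intermediate stages when requested.
#' @section Errors: propagates `empty_image_error` when a band has fewer
#'   than 3 edge pixels.
#' @export
detect_foot_parabolas <- function(img, params = umda_params(), radius = 3L,
                                  low = NULL, high = NULL, flip = FALSE,
                                  keep_stages = FALSE) {
  smooth <- mean_filter(img)
  edges <- canny_edges(smooth, low = low, high = high)
  binary <- dilate_edges(edges, radius = radius)
  sections <- section_foot(binary$grid, flip = flip)

  detect_band <- function(band, band_seed_shift) {
    p <- params
    if (!is.null(p$seed)) p$seed <- p$seed + band_seed_shift
    res <- detect_parabola_umda(band$pixels, p, orientation = "y_of_x")
    res$row_offset <- band$row_offset
    if (!is.null(res$parabola)) {
      va <- vertex_aperture(res$parabola)
      res$vertex <- c(x = va$vertex_x, y = va$vertex_y + band$row_offset)
    }
    res
  }
  out <- list(arch = detect_band(sections$arch, 0L),
              heel = detect_band(sections$heel, 1L))
  if (keep_stages) {
    out$stages <- list(smooth = smooth, edges = edges, binary = binary)
  }
  out
}
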