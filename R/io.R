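#' Read a grayscale image from PNG or TIFF
#'
#' Color images are converted to luminance (0.2126 R + 0.7152 G +
#' 0.0722 B); values are returned in `[0, 1]`.
#'
#' @param path PNG or TIFF file path.
#' @return Numeric intensity matrix.
#' @export
read_gray_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  a <- if (ext %in% c("tif", "tiff")) {
    EBImage::imageData(EBImage::readImage(path))
  } else {
    png::readPNG(path)
  }
  if (length(dim(a)) == 3L) {
    if (dim(a)[3] >= 3L) {
      a <- 0.2126 * a[, , 1] + 0.7152 * a[, , 2] + 0.0722 * a[, , 3]
    } else {
      a <- a[, , 1]
    }
  }
  m <- as.matrix(a)
  # EBImage stores images x-major (columns first); PNG is row-major already
  if (ext %in% c("tif", "tiff")) m <- t(m)
  m
}

#' Write a synthetic scene to PNG with a truth sidecar
#'
#' The binary image goes to `<stem>.png` and the ground truth (planted
#' coefficients, vertex, aperture, distractor descriptors, noise
#' fraction, seed) to `<stem>.json`.
#'
#' @param scene A `"synthetic_scene"`.
#' @param stem Output path without extension.
#' @return Invisibly, the two paths written.
#' @export
write_scene <- function(scene, stem) {
  stopifnot(inherits(scene, "synthetic_scene"))
  png_path <- paste0(stem, ".png")
  json_path <- paste0(stem, ".json")
  png::writePNG(scene$image$grid * 1.0, png_path)
  va <- vertex_aperture(scene$truth)
  obj <- list(truth = list(A = scene$truth$A, B = scene$truth$B,
                           C = scene$truth$C,
                           orientation = scene$truth$orientation,
                           vertex_x = va$vertex_x, vertex_y = va$vertex_y,
                           four_p = va$four_p),
              distractors = scene$distractors,
              noise_fraction = scene$noise_fraction,
              seed = scene$seed)
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA,
                              null = "null"), json_path)
  invisible(c(png = png_path, json = json_path))
}

#' Read a scene written by [write_scene()]
#'
#' @param stem Path stem used at write time.
#' @return A `"synthetic_scene"`.
#' @export
read_scene <- function(stem) {
  grid <- png::readPNG(paste0(stem, ".png"))
  if (length(dim(grid)) == 3L) grid <- grid[, , 1]
  meta <- jsonlite::fromJSON(paste0(stem, ".json"), simplifyVector = FALSE)
  truth <- parabola(meta$truth$A, meta$truth$B, meta$truth$C,
                    orientation = meta$truth$orientation)
  structure(list(image = edge_image(round(grid)), truth = truth,
                 distractors = meta$distractors,
                 noise_fraction = meta$noise_fraction,
                 seed = meta$seed),
            class = "synthetic_scene")
}

#' Write a scene battery with its manifest
#'
#' Writes every scene as PNG + truth JSON under `dir` and a
#' `manifest.csv` listing scene id, base scene, seed, noise level and
#' truth coefficients.
#'
#' @param scenes List of `"synthetic_scene"` (e.g.
#'   [build_noise_battery()] output).
#' @param dir Output directory (created if missing).
#' @return Invisibly, the manifest data frame.
#' @export
write_battery <- function(scenes, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(seq_along(scenes), function(i) {
    sc <- scenes[[i]]
    stem <- file.path(dir, sprintf("scene_%04d", i))
    write_scene(sc, stem)
    data.frame(scene = i,
               base_id = if (is.null(sc$base_id)) NA_integer_ else sc$base_id,
               seed = if (is.null(sc$seed)) NA_integer_ else sc$seed,
               noise_percent = 100 * sc$noise_fraction,
               A = sc$truth$A, B = sc$truth$B, C = sc$truth$C)
  })
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}

#' Draw a detected parabola over an image and save as PNG
#'
#' Writes an RGB overlay with the input edge map in gray and the
#' detected curve in red, for visual inspection of a detection.
#'
#' @param img An [edge_image()] or binary matrix.
#' @param p A [parabola()].
#' @param path Output PNG path.
#' @return Invisibly, `path`.
#' @export
write_overlay <- function(img, p, path) {
  img <- as_edge_image(img)
  h <- nrow(img$grid); w <- ncol(img$grid)
  curve <- rasterize(p, h, w)$grid
  base <- img$grid * 0.6
  rgb <- array(0, dim = c(h, w, 3))
  rgb[, , 1] <- pmax(base, curve)
  rgb[, , 2] <- base * (1 - curve)
  rgb[, , 3] <- base * (1 - curve)
  png::writePNG(rgb, path)
  invisible(path)
}
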