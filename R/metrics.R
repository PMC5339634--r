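#' RMSD fit report between two parabolas
#'
#' Compares the planted and detected curves row by row over
#' `t = 0..height-1` on their functional forms:
#' `rmsd_raw = sqrt(mean((x_real - x_detected)^2))` in pixels.  The
#' matched-point count is the cardinality of rows where the rounded
#' columns coincide, and the normalized RMSD divides the raw value by
#' that cardinality -- the convention that rewards fits with many
#' matched points.  When no row matches, the normalized value is `Inf`
#' and flagged.
#'
#' @param truth,detected Two [parabola()]s sharing an orientation.
#' @param height Number of quadratic-argument samples (frame extent
#'   along the quadratic axis).
#' @param in_frame_only When `TRUE`, restrict the comparison to rows
#'   where both rounded curves fall inside `[0, width)`; requires
#'   `width`.
#' @param width Frame extent of the dependent axis (needed only for
#'   `in_frame_only`).
#' @return A list of class `"fit_report"`: `rmsd_raw`,
#'   `rmsd_normalized`, `matched_points`, `n_compared`, `no_match`
#'   (flag), `vertex_x`, `vertex_y`, `four_p` of the detected curve.
#' @export
rmsd_report <- function(truth, detected, height, in_frame_only = FALSE,
                        width = NULL) {
  stopifnot(inherits(truth, "parabola"), inherits(detected, "parabola"),
            height >= 1)
  if (truth$orientation != detected$orientation) {
    stop("curves have different orientations and cannot be compared row-wise")
  }
  t <- 0:(height - 1L)
  xr <- parabola_eval(truth, t)
  xd <- parabola_eval(detected, t)
  if (in_frame_only) {
    stopifnot(!is.null(width))
    keep <- round_half_away(xr) >= 0 & round_half_away(xr) < width &
            round_half_away(xd) >= 0 & round_half_away(xd) < width
    xr <- xr[keep]; xd <- xd[keep]
  }
  n <- length(xr)
  raw <- if (n == 0) NA_real_ else sqrt(mean((xr - xd)^2))
  matched <- sum(round_half_away(xr) == round_half_away(xd))
  va <- vertex_aperture(detected)
  structure(list(rmsd_raw = raw,
                 rmsd_normalized = if (matched > 0) raw / matched else Inf,
                 matched_points = as.integer(matched),
                 n_compared = as.integer(n),
                 no_match = matched == 0L,
                 vertex_x = va$vertex_x, vertex_y = va$vertex_y,
                 four_p = va$four_p),
            class = "fit_report")
}

#' @export
print.fit_report <- function(x, ...) {
  cat(sprintf("fit_report: RMSD = %.4g px, normalized = %.4g, matched %d / %d rows\n",
              x$rmsd_raw, x$rmsd_normalized, x$matched_points, x$n_compared))
  invisible(x)
}

#' Overlap fraction between a detected curve and the planted curve
#'
#' How much of the planted curve the detection covers: the number of
#' detected-raster pixels falling inside the planted curve's band (its
#' rasterization dilated by `tol`, the scene thickness), divided by the
#' planted curve's in-frame pixel count and capped at 1.  A detection
#' that tracks the planted band across its full extent scores near 1; a
#' curve locked onto a distractor scores near 0.  This is the recovery
#' criterion used by the noise sweep and the repeated-run experiments.
#'
#' @param truth,detected Two [parabola()]s with the same orientation.
#' @param height,width Frame size in pixels.
#' @param tol Band half-width in pixels (default 3, the scene dilation
#'   radius); `tol = 0` demands exact raster coincidence.
#' @return A number in `[0, 1]`; `NA` when the planted curve has no
#'   in-frame pixels.
#' @export
overlap_fraction <- function(truth, detected, height, width, tol = 3) {
  stopifnot(inherits(truth, "parabola"), inherits(detected, "parabola"),
            truth$orientation == detected$orientation)
  truth_ras <- rasterize(truth, height, width)
  if (truth_ras$N == 0L) return(NA_real_)
  band <- if (tol > 0) dilate_grid(truth_ras$grid, as.integer(tol))
          else truth_ras$grid
  det_ras <- rasterize(detected, height, width)
  min(1, sum(det_ras$grid * band) / truth_ras$N)
}

#' Matched points between a truth image and a detected curve
#'
#' The "matched points" statistic of the benchmark tables: the Hadamard
#' fitness of the detected parabola against the (truth) edge image.
#'
#' @param truth_img An [edge_image()] or binary matrix.
#' @param detected A [parabola()].
#' @return Non-negative integer count.
#' @export
matched_points_image <- function(truth_img, detected) {
  hadamard_fitness(truth_img, detected)
}

#' Run the detection benchmark over a scene battery
#'
#' For every scene and method, runs the detector `n_runs` times with
#' per-run seeds derived deterministically from `seed`, and records the
#' fitness, the iteration statistics and the RMSD fit report against the
#' planted truth.  Returns both the per-run log and a summary in the
#' min/max/mean/median shape of the benchmark tables; the summary is
#' recomputable from the log.
#'
#' @param scenes List of `"synthetic_scene"` objects (e.g. from
#'   [build_noise_battery()]).
#' @param methods Character subset of `c("umda", "ransac", "hough")`.
#' @param n_runs Detection repetitions per scene and method (default
#'   30).  Hough voting is deterministic, so it runs once per scene.
#' @param params An [umda_params()] for the UMDA runs.
#' @param ransac An optional [ransac_params()].
#' @param grid An optional [hough_grid()]; default spans each frame.
#' @param seed Master seed for the per-run seed stream.
#' @return A list with data frames `runs` (one row per run) and
#'   `summary` (min/max/mean/median of iterations and fitness per scene
#'   and method).
#' @export
run_benchmark <- function(scenes, methods = c("umda"), n_runs = 30L,
                          params = umda_params(), ransac = ransac_params(),
                          grid = NULL, seed = 1L) {
  stopifnot(length(scenes) >= 1, n_runs >= 1,
            all(methods %in% c("umda", "ransac", "hough")))
  set.seed(seed)
  run_seeds <- sample.int(.Machine$integer.max,
                          length(scenes) * length(methods) * n_runs)
  rows <- list()
  k <- 0L
  si <- 0L
  for (sc_id in seq_along(scenes)) {
    sc <- scenes[[sc_id]]
    h <- nrow(sc$image$grid); w <- ncol(sc$image$grid)
    for (m in methods) {
      reps <- if (m == "hough") 1L else n_runs
      for (r in seq_len(reps)) {
        si <- si + 1L
        res <- switch(m,
          umda = {
            p <- params; p$seed <- run_seeds[si]
            detect_parabola_umda(sc$image, p)
          },
          ransac = {
            p <- ransac; p$seed <- run_seeds[si]
            detect_parabola_ransac(sc$image, p)
          },
          hough = {
            g <- if (is.null(grid)) default_hough_grid(h, w) else grid
            hres <- detect_parabola_hough(sc$image, g)
            structure(list(parabola = hres$parabola,
                           fitness = hres$votes,
                           generations = NA_integer_,
                           best_generation = NA_integer_,
                           evaluations = NA_integer_,
                           method = "hough"),
                      class = "detection_result")
          })
        rep_ <- if (!is.null(res$parabola)) {
          rmsd_report(sc$truth, res$parabola, h)
        } else {
          list(rmsd_raw = NA_real_, rmsd_normalized = NA_real_,
               matched_points = NA_integer_)
        }
        k <- k + 1L
        rows[[k]] <- data.frame(
          scene = sc_id,
          noise = sc$noise_fraction,
          method = m,
          run = r,
          seed = run_seeds[si],
          fitness = res$fitness,
          generations = res$generations,
          iterations = res$best_generation,
          evaluations = res$evaluations,
          rmsd = rep_$rmsd_raw,
          urmsd = rep_$rmsd_raw,            # unnormalized, table vocabulary
          rmsd_normalized = rep_$rmsd_normalized,
          matched_points = rep_$matched_points)
      }
    }
  }
  runs <- do.call(rbind, rows)
  agg <- function(v) c(min = suppressWarnings(min(v, na.rm = TRUE)),
                       max = suppressWarnings(max(v, na.rm = TRUE)),
                       mean = mean(v, na.rm = TRUE),
                       median = stats::median(v, na.rm = TRUE))
  summ <- do.call(rbind, lapply(
    split(runs, interaction(runs$scene, runs$method, drop = TRUE)),
    function(d) {
      it <- agg(d$iterations); fit <- agg(d$fitness)
      data.frame(scene = d$scene[1], noise = d$noise[1], method = d$method[1],
                 n_runs = nrow(d),
                 iterations_min = it["min"], iterations_max = it["max"],
                 iterations_mean = it["mean"], iterations_median = it["median"],
                 fitness_min = fit["min"], fitness_max = fit["max"],
                 fitness_mean = fit["mean"], fitness_median = fit["median"],
                 rmsd_mean = mean(d$rmsd, na.rm = TRUE),
                 row.names = NULL)
    }))
  rownames(summ) <- NULL
  list(runs = runs, summary = summ)
}
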