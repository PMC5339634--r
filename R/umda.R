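#' UMDA optimizer parameters
#'
#' Defaults follow the parameter set used for all detection experiments:
#' 10 individuals per generation, selection rate 0.6, at most 30
#' generations.
#'
#' @param n_individuals Population size (default 10).
#' @param selection_rate Fraction of the population kept for the
#'   marginal-probability update, in (0, 1] (default 0.6).
#' @param max_generations Generation budget (default 30).
#' @param seed Optional integer seed; when given, the whole run is
#'   reproducible bit for bit.
#' @return A list of class `"umda_params"`.
#' @export
umda_params <- function(n_individuals = 10L, selection_rate = 0.6,
                        max_generations = 30L, seed = NULL) {
  stopifnot(n_individuals >= 2, selection_rate > 0, selection_rate <= 1,
            max_generations >= 1)
  structure(list(n_individuals = as.integer(n_individuals),
                 selection_rate = selection_rate,
                 max_generations = as.integer(max_generations),
                 seed = seed),
            class = "umda_params")
}

#' Encode a pixel-index triplet as a bit string
#'
#' Each of the three indices is written as an L-bit binary number,
#' most-significant bit first, and the three genes are concatenated
#' `i | j | k` into a single 3L-bit chromosome.  For example, with L = 8
#' the triplet `{22, 58, 39}` becomes
#' `000101100011101000100111`.
#'
#' @param indices Integer vector of length 3, each in `[0, 2^L)`.
#' @param L Bits per gene.
#' @return Integer vector of 0/1 of length `3 * L`.
#' @export
encode_indices <- function(indices, L) {
  stopifnot(length(indices) == 3L, L >= 1, L <= 30)
  if (any(indices < 0) || any(indices >= 2^L)) {
    stop(sprintf("index out of range for %d-bit encoding", L))
  }
  as.integer(unlist(lapply(indices, function(idx) {
    rev(as.integer(intToBits(as.integer(idx)))[seq_len(L)])
  })))
}

#' Decode a bit string back to a pixel-index triplet
#'
#' Inverse of [encode_indices()]: splits the chromosome into three L-bit
#' genes (most-significant bit first) and returns their integer values.
#' Validity against the number of foreground pixels N is the caller's
#' concern.
#'
#' @param bits Integer 0/1 vector of length `3 * L`.
#' @param L Bits per gene.
#' @return Integer vector of length 3.
#' @export
decode_indices <- function(bits, L) {
  if (length(bits) != 3L * L) {
    stop(sprintf("bit string has length %d, expected 3*L = %d",
                 length(bits), 3L * L))
  }
  w <- 2^((L - 1L):0)
  vapply(0:2, function(g) sum(bits[g * L + seq_len(L)] * w), numeric(1))
}

#' Hadamard-product fitness of a candidate parabola
#'
#' The fitness of a candidate is the number of white pixels in the
#' Hadamard (elementwise) product between the binary input image
#' f_binary and the virtual shape I_VS, i.e. the count of pixels where
#' the rasterized candidate and the edge image are both foreground.
#'
#' @param img An [edge_image()] (or binary matrix), the f_binary input.
#' @param candidate A [parabola()] in the image's frame.
#' @return Non-negative integer matched-pixel count.
#' @export
hadamard_fitness <- function(img, candidate) {
  img <- as_edge_image(img)
  stopifnot(inherits(candidate, "parabola"))
  fitness_fast(img$grid, candidate$A, candidate$B, candidate$C,
               candidate$orientation)
}

# vectorized fitness without materializing I_VS; provably equal to
# sum(rasterize(p) * grid) because both use the same per-row rounding
fitness_fast <- function(grid, A, B, C, orientation = "x_of_y") {
  h <- nrow(grid); w <- ncol(grid)
  if (orientation == "x_of_y") {
    t <- 0:(h - 1L)
    x <- round_half_away(A * t * t + B * t + C)
    ok <- is.finite(x) & x >= 0 & x < w
    if (!any(ok)) return(0L)
    sum(grid[cbind(t[ok] + 1L, x[ok] + 1L)])
  } else {
    t <- 0:(w - 1L)
    y <- round_half_away(A * t * t + B * t + C)
    ok <- is.finite(y) & y >= 0 & y < h
    if (!any(ok)) return(0L)
    sum(grid[cbind(y[ok] + 1L, t[ok] + 1L)])
  }
}

#' Fitness of one encoded individual
#'
#' Decodes the chromosome, looks up the three pixels, fits the
#' interpolating parabola and returns its Hadamard fitness.  All failure
#' modes -- an index at or beyond N, a repeated index, a degenerate
#' triplet (shared row or collinear pixels) -- score 0 rather than
#' erroring, keeping the evolutionary loop total.
#'
#' @param bits Integer 0/1 chromosome of length `3 * L`.
#' @param img An [edge_image()].
#' @param L Bits per gene, `ceiling(log2(img$N))`.
#' @return Non-negative integer fitness.
#' @export
evaluate_individual <- function(bits, img, L) {
  img <- as_edge_image(img)
  idx <- decode_indices(bits, L)
  if (any(idx >= img$N) || anyDuplicated(idx) > 0L) return(0L)
  pts <- img$foreground[idx + 1L, , drop = FALSE]
  p <- tryCatch(
    fit_three_points(pts[1L, ], pts[2L, ], pts[3L, ]),
    degenerate_triplet_error = function(e) NULL)
  if (is.null(p)) return(0L)
  fitness_fast(img$grid, p$A, p$B, p$C)
}

#' Truncation selection of the best individuals
#'
#' Keeps the top `ceiling(rate * n)` individuals by fitness.  Ties are
#' broken by earlier population position and the survivors keep their
#' relative order, so selection is fully deterministic.
#'
#' @param population Matrix of chromosomes, one row per individual.
#' @param fitness Numeric vector of matching length.
#' @param rate Selection rate in (0, 1].
#' @return Matrix of the selected rows.
#' @export
select_best <- function(population, fitness, rate) {
  stopifnot(is.matrix(population), nrow(population) == length(fitness),
            rate > 0, rate <= 1)
  k <- ceiling(rate * nrow(population))
  ord <- order(-fitness, seq_along(fitness))  # stable: position breaks ties
  keep <- sort(ord[seq_len(k)])               # survivors keep original order
  population[keep, , drop = FALSE]
}

#' Marginal-probability estimate from selected individuals
#'
#' The UMDA model is the fully factorized distribution
#' \eqn{P(x) = \prod_i P(X_i = x_i)}: each bit's marginal is the
#' frequency of ones at that position among the selected individuals.
#' Marginals are clamped to `[1/(3L), 1 - 1/(3L)]` so no bit locks in
#' prematurely.
#'
#' @param selected Matrix of selected chromosomes (rows).
#' @param clamp Clamping margin; default `1 / ncol(selected)`.
#' @return Numeric probability vector of length `ncol(selected)`.
#' @export
estimate_probabilities <- function(selected, clamp = 1 / ncol(selected)) {
  stopifnot(is.matrix(selected), nrow(selected) >= 1)
  p <- colMeans(selected)
  pmin(pmax(p, clamp), 1 - clamp)
}

#' Sample a population from the marginal-probability vector
#'
#' Draws each bit independently as Bernoulli(prob[b]).  A gene whose
#' decoded index falls at or beyond N is re-drawn from the same marginals
#' (up to 16 attempts) and finally replaced by a uniformly chosen valid
#' index; remapping by modulo would bias the search toward low scan-order
#' pixels.
#'
#' @param prob Probability vector of length `3 * L`.
#' @param n Number of individuals to draw.
#' @param N Number of valid pixel indices (genes must decode `< N`).
#' @param L Bits per gene.
#' @return `n x 3L` integer matrix of chromosomes.
#' @export
sample_population <- function(prob, n, N, L) {
  stopifnot(length(prob) == 3L * L, all(prob >= 0), all(prob <= 1))
  pop <- matrix(0L, nrow = n, ncol = 3L * L)
  w <- 2^((L - 1L):0)
  for (i in seq_len(n)) {
    for (g in 0:2) {
      seg <- g * L + seq_len(L)
      ok <- FALSE
      for (attempt in 1:16) {
        bits <- as.integer(stats::runif(L) < prob[seg])
        if (sum(bits * w) < N) { ok <- TRUE; break }
      }
      if (!ok) {
        bits <- rev(as.integer(intToBits(sample.int(N, 1L) - 1L))[seq_len(L)])
      }
      pop[i, seg] <- bits
    }
  }
  pop
}

#' Detect a parabola with the UMDA
#'
#' The full detection loop: foreground pixels are indexed `0..N-1` and a
#' population of 3-index individuals, encoded as `3 * ceiling(log2(N))`
#' bit chromosomes, evolves under truncation selection and the
#' factorized marginal model.  Each individual is scored by the Hadamard
#' product between its interpolating parabola's raster and the edge
#' image.  The run stops at the generation budget, when every marginal
#' has reached its clamp bound, or when the population fitness has zero
#' standard deviation; the best individual found anywhere along the
#' process is returned.
#'
#' @param img An [edge_image()] or binary matrix with at least 3
#'   foreground pixels.
#' @param params An [umda_params()].
#' @param orientation `"x_of_y"` detects a sideways parabola
#'   `x = A y^2 + B y + C`; `"y_of_x"` transposes the image, detects,
#'   and maps the result back to the upright form.
#' @param init_population Optional chromosome matrix
#'   (`n_individuals x 3L`) used as generation 1 instead of sampling
#'   from the uniform model; mainly for controlled experiments.
#' @return A list of class `"detection_result"`: `parabola`, `indices`
#'   (0-based pixel indices of the best individual), `fitness`,
#'   `generations` (executed), `best_generation` (last improvement of
#'   the global best -- the "iterations" statistic of the benchmark
#'   tables), `evaluations` (`n_individuals * generations`), `history`
#'   (best-so-far fitness per generation) and `elapsed` seconds
#'   (informational only).
#' @section Errors: `empty_image_error` when `N < 3`.
#' @examples
#' truth <- parabola(0.02, -2, 60)
#' img <- rasterize(truth, 100, 100)
#' res <- detect_parabola_umda(img, umda_params(seed = 1))
#' res$fitness
#' @export
detect_parabola_umda <- function(img, params = umda_params(),
                                 orientation = c("x_of_y", "y_of_x"),
                                 init_population = NULL) {
  orientation <- match.arg(orientation)
  stopifnot(inherits(params, "umda_params"))
  img <- as_edge_image(img)
  if (orientation == "y_of_x") img <- transpose_edge_image(img)
  if (img$N < 3L) {
    stop(empty_image_error(sprintf(
      "edge image has %d foreground pixel(s); at least 3 are required",
      img$N)))
  }
  if (!is.null(params$seed)) set.seed(params$seed)
  t0 <- proc.time()[["elapsed"]]

  N <- img$N
  L <- max(2L, as.integer(ceiling(log2(N))))
  nb <- 3L * L
  clamp <- 1 / nb
  n <- params$n_individuals
  prob <- rep(0.5, nb)

  best_bits <- NULL
  best_fit <- -1L
  best_gen <- 0L
  gen <- 0L
  history <- integer(0)

  repeat {
    gen <- gen + 1L
    pop <- if (gen == 1L && !is.null(init_population)) {
      stopifnot(is.matrix(init_population), ncol(init_population) == nb)
      init_population
    } else {
      sample_population(prob, n, N, L)
    }
    fitness <- vapply(seq_len(nrow(pop)),
                      function(i) evaluate_individual(pop[i, ], img, L),
                      integer(1))
    imax <- which.max(fitness)
    if (fitness[imax] > best_fit) {
      best_fit <- fitness[imax]
      best_bits <- pop[imax, ]
      best_gen <- gen
    }
    history <- c(history, best_fit)
    if (gen >= params$max_generations) break
    selected <- select_best(pop, fitness, params$selection_rate)
    prob <- estimate_probabilities(selected, clamp = clamp)
    converged <- all(prob <= clamp + 1e-12 | prob >= 1 - clamp - 1e-12)
    if (converged || stats::sd(fitness) == 0) break
  }

  idx <- decode_indices(best_bits, L)
  pts <- img$foreground[idx + 1L, , drop = FALSE]
  best_par <- tryCatch(
    fit_three_points(pts[1L, ], pts[2L, ], pts[3L, ]),
    degenerate_triplet_error = function(e) NULL)
  if (!is.null(best_par) && orientation == "y_of_x") {
    best_par <- parabola(best_par$A, best_par$B, best_par$C,
                         orientation = "y_of_x")
  }
  structure(list(parabola = best_par,
                 indices = as.integer(idx),
                 fitness = as.integer(best_fit),
                 generations = gen,
                 best_generation = best_gen,
                 evaluations = n * gen,
                 history = history,
                 method = "umda",
                 elapsed = proc.time()[["elapsed"]] - t0),
            class = "detection_result")
}

#' @export
print.detection_result <- function(x, ...) {
  cat(sprintf("detection_result (%s): fitness = %d, generations = %d (best at %d), evaluations = %d\n",
              x$method, x$fitness, x$generations, x$best_generation,
              x$evaluations))
  if (!is.null(x$parabola)) print(x$parabola)
  invisible(x)
}

#' Serialize a detection result to JSON
#'
#' @param res A `"detection_result"`.
#' @param path Optional output file.
#' @return JSON string (invisibly when written).
#' @export
detection_json <- function(res, path = NULL) {
  stopifnot(inherits(res, "detection_result"))
  p <- res$parabola
  va <- if (!is.null(p)) vertex_aperture(p) else
    list(vertex_x = NA, vertex_y = NA, four_p = NA)
  obj <- list(method = res$method,
              A = if (is.null(p)) NA else p$A,
              B = if (is.null(p)) NA else p$B,
              C = if (is.null(p)) NA else p$C,
              orientation = if (is.null(p)) NA else p$orientation,
              vertex_x = va$vertex_x, vertex_y = va$vertex_y,
              four_p = va$four_p,
              fitness = res$fitness,
              generations = res$generations,
              best_generation = res$best_generation,
              evaluations = res$evaluations)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
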