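# shared fixture builders; everything is generated in code at test time

# a random nondegenerate sideways parabola with moderate coefficients
random_parabola <- function() {
  A <- sample(c(-1, 1), 1) * runif(1, 0.005, 0.5)
  parabola(A, runif(1, -5, 5), runif(1, -50, 50))
}

# independent 3x3 linear-system oracle for the three-point fit
solve_fit_oracle <- function(pts) {
  X <- cbind(pts[, 2]^2, pts[, 2], 1)
  as.numeric(solve(X, pts[, 1]))
}

# dense Hadamard oracle: materialize I_VS and elementwise-multiply
dense_fitness_oracle <- function(img, p) {
  ivs <- rasterize(p, nrow(img$grid), ncol(img$grid))
  sum(img$grid * ivs$grid)
}

# a small random binary image with at least `min_fg` foreground pixels
random_binary_image <- function(h = 40, w = 40, density = 0.15, min_fg = 3) {
  repeat {
    g <- matrix(as.integer(runif(h * w) < density), h, w)
    if (sum(g) >= min_fg) return(edge_image(g))
  }
}
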