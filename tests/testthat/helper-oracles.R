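# Independent brute-force oracles and small fixture builders.

# Brute-force optimal proper rotation by dense angular grid search:
# minimizes ||X R(theta) - Y|| over theta. Returns list(angle, distance).
grid_rotation_oracle <- function(x, y, step = 1e-4) {
  theta <- seq(-pi, pi, by = step)
  # with R = rot2(t): ||X R - Y||^2 = ||X||^2 + ||Y||^2 - 2 (a cos t + b sin t)
  a <- sum(x * y)
  b <- sum(x[, 2] * y[, 1] - x[, 1] * y[, 2])
  # evaluate the objective on the grid only (no closed-form maximization):
  obj <- sum(x^2) + sum(y^2) - 2 * (a * cos(theta) + b * sin(theta))
  i <- which.min(obj)
  list(angle = theta[i], distance = sqrt(max(0, obj[i])))
}

# Fully independent grid oracle that evaluates the residual norm directly
# (no use of the a/b reduction); slower, for small cases.
grid_rotation_oracle_direct <- function(x, y, step = 1e-3) {
  theta <- seq(-pi, pi, by = step)
  obj <- vapply(theta, function(t) {
    r <- matrix(c(cos(t), sin(t), -sin(t), cos(t)), 2)
    sum((x %*% r - y)^2)
  }, numeric(1))
  i <- which.min(obj)
  list(angle = theta[i], distance = sqrt(obj[i]))
}

rotation_angle <- function(r) atan2(r[2, 1], r[1, 1])

rot2 <- function(theta) {
  matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2)
}

# random non-degenerate k x 2 configuration
random_config <- function(k = 18) {
  matrix(stats::rnorm(2 * k), ncol = 2)
}

# apply a random similarity transform (never a reflection)
random_similarity <- function(m) {
  theta <- stats::runif(1, -pi, pi)
  s <- exp(stats::runif(1, -1, 1))
  tr <- stats::runif(2, -5, 5)
  sweep(s * m %*% rot2(theta), 2, tr, "+")
}

# small labeled landmark tibble: `sizes` named vector, shapes = base shape
# plus per-group offset on landmark 1, plus noise
tiny_dataset <- function(sizes = c(A = 5, B = 5), noise = 0.01,
                         offset = 0.3, k = 6) {
  base <- to_preshape(cbind(cos(seq_len(k)), sin(seq_len(k) * 2)))
  rows <- list()
  idx <- 0
  for (gi in seq_along(sizes)) {
    g <- names(sizes)[gi]
    shift <- matrix(0, k, 2)
    shift[gi, 1] <- offset
    for (i in seq_len(sizes[gi])) {
      idx <- idx + 1
      m <- base + shift + matrix(stats::rnorm(2 * k, sd = noise), ncol = 2)
      rows[[idx]] <- landmark_data(m, sprintf("%s%02d", g, i), group = g)
    }
  }
  dplyr::bind_rows(rows)
}
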