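#' Convert a configuration to a preshape
#'
#' Centers a k x 2 coordinate matrix at the origin and scales it to unit
#' centroid size. Preshapes are the points of the preshape sphere on which
#' Procrustes distances are computed.
#'
#' @param m a k x 2 numeric matrix with at least two distinct landmarks.
#' @return a k x 2 matrix with centroid at the origin and centroid size 1.
#' @export
to_preshape <- function(m) {
  m <- as.matrix(m)
  cs <- centroid_size(m)  # errors on degenerate input
  out <- sweep(m, 2, colMeans(m)) / cs
  colnames(out) <- c("x", "y")
  out
}

#' Optimal proper rotation between two preshapes
#'
#' Returns the 2 x 2 rotation matrix `R` (det = +1; reflections disallowed)
#' minimizing `||source %*% R - target||`, computed from the singular value
#' decomposition of the cross-product matrix `t(source) %*% target`.
#'
#' @param source,target k x 2 preshape matrices with matching k.
#' @return a 2 x 2 proper rotation matrix.
#' @export
optimal_rotation <- function(source, target) {
  if (nrow(source) != nrow(target)) {
    stop("configurations have different landmark counts", call. = FALSE)
  }
  s <- crossprod(source, target)
  sv <- svd(s)
  d <- sign(det(sv$u %*% t(sv$v)))
  sv$u %*% diag(c(1, d)) %*% t(sv$v)
}

# Internal: for 2-D shapes the optimal-rotation problem has a closed form.
# With S = t(X) %*% Y, the maximal inner product over proper rotations is
# sqrt((s11+s22)^2 + (s12-s21)^2); the optimal angle has cos/sin proportional
# to those two terms. Used (vectorized) inside gpa() and the distances.
opt_inner <- function(x, y) {
  a <- sum(x * y)
  b <- sum(x[, 1] * y[, 2] - x[, 2] * y[, 1])
  sqrt(a * a + b * b)
}

#' Procrustes distance between two shapes
#'
#' Both inputs are reduced to preshapes, then compared at the optimal proper
#' rotation. `metric = "partial"` is the Euclidean norm of the residual
#' `a R - b`; `metric = "rho"` is the arc (geodesic) distance
#' `acos(<aR, b>)` on the preshape sphere. Both are zero exactly when the two
#' shapes are identical up to translation, positive scaling and rotation
#' (reflections are never fitted).
#'
#' @param a,b k x 2 coordinate matrices (any position/scale/orientation).
#' @param metric `"partial"` or `"rho"`.
#' @return a non-negative scalar.
#' @export
procrustes_distance <- function(a, b, metric = c("partial", "rho")) {
  metric <- match.arg(metric)
  if (nrow(a) != nrow(b)) {
    stop("configurations have different landmark counts", call. = FALSE)
  }
  pa <- to_preshape(a)
  pb <- to_preshape(b)
  d <- min(1, max(-1, opt_inner(pa, pb)))
  if (metric == "rho") acos(d) else sqrt(max(0, 2 - 2 * d))
}

#' Generalized Procrustes superimposition
#'
#' Iterative generalized least-squares superimposition: all configurations
#' are centered and scaled to unit centroid size (partial Procrustes: no
#' residual per-specimen scale fitting), the consensus is initialized from
#' the first specimen, and rotation-to-consensus / consensus-recomputation
#' steps alternate until the consensus moves less than `tol` (partial
#' Procrustes distance) or `max_iter` is reached. The final aligned set is
#' rotated so the consensus's major principal axis is horizontal, which
#' removes the global-rotation gauge freedom and makes output deterministic.
#'
#' @param data a landmark tibble with at least two specimens.
#' @param tol convergence tolerance on consensus movement.
#' @param max_iter maximum number of iterations.
#' @return an object of class `gpa` with elements `consensus` (k x 2 unit
#'   preshape), `aligned` (k x 2 x n array of aligned preshapes),
#'   `centroid_sizes` (tibble), `meta` (per-specimen metadata tibble),
#'   `iterations`, `converged`, and `ss_trace` (sum of squared deviations
#'   from the consensus at each iteration, non-increasing).
#' @export
gpa <- function(data, tol = 1e-8, max_iter = 100) {
  sp <- lm_split(data)
  n <- length(sp$ids)
  if (n < 2) stop("superimposition needs at least 2 specimens", call. = FALSE)
  k <- sp$k
  cs <- apply(sp$coords, 3, centroid_size)
  pre <- sp$coords
  for (i in seq_len(n)) pre[, , i] <- to_preshape(sp$coords[, , i])

  consensus <- pre[, , 1]
  ss_trace <- numeric(0)
  converged <- FALSE
  iter <- 0L
  aligned <- pre
  while (iter < max_iter) {
    iter <- iter + 1L
    aligned <- rotate_all_to(aligned, consensus)
    new_consensus <- apply(aligned, c(1, 2), mean)
    new_consensus <- new_consensus / centroid_size(new_consensus)
    ss_trace <- c(ss_trace,
                  sum((aligned - array(new_consensus, dim(aligned)))^2))
    moved <- procrustes_distance(consensus, new_consensus, "partial")
    consensus <- new_consensus
    if (moved < tol) { converged <- TRUE; break }
  }
  if (!converged) {
    warning(sprintf("superimposition did not converge in %d iterations",
                    max_iter), call. = FALSE)
  }
  aligned <- rotate_all_to(aligned, consensus)

  # deterministic gauge: principal axis of the consensus horizontal,
  # first landmark in the right half-plane
  pc <- eigen(stats::cov(consensus), symmetric = TRUE)$vectors
  if (det(pc) < 0) pc[, 2] <- -pc[, 2]
  consensus <- consensus %*% pc
  for (i in seq_len(n)) aligned[, , i] <- aligned[, , i] %*% pc
  if (consensus[1, 1] < 0) {
    flip <- diag(c(-1, -1))
    consensus <- consensus %*% flip
    for (i in seq_len(n)) aligned[, , i] <- aligned[, , i] %*% flip
  }
  dimnames(aligned) <- list(NULL, c("x", "y"), sp$ids)
  colnames(consensus) <- c("x", "y")

  structure(list(
    consensus = consensus,
    aligned = aligned,
    centroid_sizes = tibble::tibble(specimen_id = sp$ids, centroid_size = cs),
    meta = sp$meta,
    k = k,
    n = n,
    iterations = iter,
    converged = converged,
    ss_trace = ss_trace
  ), class = "gpa")
}

# Internal: rotate every slab of a k x 2 x n array onto `target` by its
# optimal proper rotation (closed form for planar shapes).
rotate_all_to <- function(arr, target) {
  n <- dim(arr)[3]
  tx <- target[, 1]; ty <- target[, 2]
  for (i in seq_len(n)) {
    x <- arr[, 1, i]; y <- arr[, 2, i]
    a <- sum(x * tx + y * ty)
    b <- sum(x * ty - y * tx)
    h <- sqrt(a * a + b * b)
    if (h == 0) next
    co <- a / h; si <- b / h
    arr[, 1, i] <- x * co - y * si
    arr[, 2, i] <- x * si + y * co
  }
  arr
}

#' @export
print.gpa <- function(x, ...) {
  cat(sprintf(
    "Generalized Procrustes superimposition: %d specimens, %d landmarks\n",
    x$n, x$k))
  cat(sprintf("  converged: %s after %d iteration(s)\n",
              ifelse(x$converged, "yes", "NO"), x$iterations))
  cat(sprintf("  residual sum of squares: %.6g\n",
              x$ss_trace[length(x$ss_trace)]))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy aligned coordinates from a superimposition
#' @param x a `gpa` object.
#' @param ... unused.
#' @return a long tibble of aligned coordinates (one row per landmark per
#'   specimen) with metadata columns.
#' @export
tidy.gpa <- function(x, ...) {
  lm_bind(x$aligned, x$meta)
}

#' One-row summary of a superimposition
#' @param x a `gpa` object.
#' @param ... unused.
#' @export
glance.gpa <- function(x, ...) {
  tibble::tibble(
    n = x$n, k = x$k, iterations = x$iterations, converged = x$converged,
    residual_ss = x$ss_trace[length(x$ss_trace)]
  )
}

#' Project aligned configurations into the tangent space at the consensus
#'
#' Each vectorized aligned preshape `x` is orthogonally projected onto the
#' hyperplane tangent to the preshape sphere at the vectorized consensus `c`
#' (a unit vector): `x' = x - (x.c - 1) c`, and expressed as the deviation
#' `x' - c`. The resulting n x 2k score matrix has rank at most `2k - 4`
#' (centering, scaling and rotation each remove degrees of freedom).
#'
#' @param fit a converged `gpa` object.
#' @return a list of class `tangent_scores` with `scores` (n x 2k matrix,
#'   columns `x1, y1, ...`), `consensus_vec`, `meta`, and `rank_bound`.
#' @export
project_to_tangent <- function(fit) {
  stopifnot(inherits(fit, "gpa"))
  if (!fit$converged) {
    warning("projecting a non-converged superimposition", call. = FALSE)
  }
  cvec <- vec_config(fit$consensus)          # unit vector: CS = 1, centered
  n <- fit$n
  X <- t(apply(fit$aligned, 3, vec_config))  # n x 2k
  lam <- X %*% cvec                          # inner products with consensus
  Xp <- X - (lam - 1) %*% t(cvec)            # tangent projection
  scores <- sweep(Xp, 2, cvec)               # deviations from tangent point
  colnames(scores) <- paste0(rep(c("x", "y"), fit$k),
                             rep(seq_len(fit$k), each = 2))
  rownames(scores) <- fit$meta$specimen_id
  structure(list(scores = scores, consensus_vec = cvec, meta = fit$meta,
                 k = fit$k, rank_bound = 2L * fit$k - 4L),
            class = "tangent_scores")
}

#' Adequacy of the tangent-space approximation
#'
#' Computes all pairwise Procrustes rho distances in shape space and all
#' pairwise Euclidean distances among the tangent-space scores, then the
#' through-origin least-squares regression slope of Euclidean on rho and
#' their uncentered correlation. Values near 1 indicate that the linear
#' tangent space is an adequate stage for multivariate statistics on the
#' sample's shape variation.
#'
#' @param fit a `gpa` object (n >= 3, nonzero shape variation).
#' @return a tibble with columns `slope`, `correlation`, `n_pairs`.
#' @export
tangent_adequacy <- function(fit) {
  stopifnot(inherits(fit, "gpa"))
  if (fit$n < 3) stop("adequacy check needs at least 3 specimens",
                      call. = FALSE)
  ts <- suppressWarnings(project_to_tangent(fit))
  euc <- as.vector(stats::dist(ts$scores))
  rho <- pairwise_rho(fit$aligned)
  if (max(rho) < 1e-7) {
    stop("no shape variation in the sample", call. = FALSE)
  }
  slope <- sum(euc * rho) / sum(rho^2)
  correlation <- sum(euc * rho) / sqrt(sum(euc^2) * sum(rho^2))
  tibble::tibble(slope = slope, correlation = correlation,
                 n_pairs = length(rho))
}

# Internal: all pairwise rho distances among aligned preshapes (closed-form
# optimal inner product; inputs are already unit preshapes).
pairwise_rho <- function(arr) {
  n <- dim(arr)[3]
  X <- arr[, 1, ]; Y <- arr[, 2, ]          # k x n each
  A <- crossprod(X) + crossprod(Y)          # dot products
  B <- crossprod(X, Y) - crossprod(Y, X)    # cross terms
  D <- sqrt(A^2 + B^2)
  D <- pmin(pmax(D, -1), 1)
  acos(D[lower.tri(D)])
}
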