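#' Principal component analysis of shape scores
#'
#' Eigendecomposition of the covariance of column-mean-centered rows (via
#' [stats::prcomp()]). Scores are projections onto the orthonormal axes;
#' percent variance is `100 * eigenvalue / total`.
#'
#' @param scores an n x p numeric matrix (rows = specimens), e.g. tangent
#'   scores.
#' @return an object of class `shape_pca` with `mean_row`, `axes`
#'   (p x m orthonormal), `eigenvalues`, `percent_variance`, `scores`
#'   (n x m).
#' @export
pca_fit <- function(scores) {
  scores <- score_matrix(scores)
  if (nrow(scores) < 2) stop("PCA needs at least 2 rows", call. = FALSE)
  pc <- stats::prcomp(scores, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  structure(list(
    mean_row = pc$center,
    axes = pc$rotation,
    eigenvalues = ev,
    percent_variance = 100 * ev / sum(ev),
    scores = pc$x
  ), class = "shape_pca")
}

#' @export
print.shape_pca <- function(x, ...) {
  cat(sprintf("Shape PCA: %d specimens, %d axes\n",
              nrow(x$scores), ncol(x$axes)))
  pv <- x$percent_variance
  cat(sprintf("  PC1 = %.1f%%, PC2 = %.1f%%\n", pv[1],
              ifelse(length(pv) > 1, pv[2], 0)))
  invisible(x)
}

#' @rdname pca_fit
#' @param x a `shape_pca` object.
#' @param ... unused.
#' @export
tidy.shape_pca <- function(x, ...) {
  tibble::tibble(
    axis = seq_along(x$eigenvalues),
    eigenvalue = x$eigenvalues,
    percent_variance = x$percent_variance,
    cumulative_percent = cumsum(x$percent_variance)
  )
}

# Internal: coerce tangent_scores / data frame / matrix to a plain matrix.
score_matrix <- function(scores) {
  if (inherits(scores, "tangent_scores")) return(scores$scores)
  if (is.data.frame(scores)) return(as.matrix(scores))
  as.matrix(scores)
}

#' Rank-safe linear discriminant model on shape scores
#'
#' Raw tangent coordinates are rank deficient (2k coordinates carry at most
#' `2k - 4` dimensions of shape variation), so the pooled within-group
#' covariance is singular on them. The model therefore first reduces the
#' input to `n_components` principal components (the `"auto"` rule keeps
#' components with eigenvalue > 1e-10 times the largest, capped at
#' `min(p, n - G - 1)`), then computes group means and the pooled
#' within-group covariance in that space, and discriminant axes from the
#' generalized eigenproblem of between- versus within-group scatter.
#'
#' @param scores n x p matrix (or `tangent_scores`) of shape variables.
#' @param labels group label per row (length n).
#' @param priors `"proportional"` (to group sizes), `"equal"`, or an explicit
#'   named numeric vector summing to 1.
#' @param n_components `"auto"` or a positive integer number of retained PCs.
#' @return an object of class `shape_lda`; see Details.
#' @details The returned object carries `groups` (ordered labels), `priors`,
#'   `pc_center`/`pc_rotation` (the retained-PC transform applied before
#'   discrimination), `group_means`, `pooled_covariance` (and its inverse),
#'   `discriminant_axes` (up to G-1), and `m` (retained dimension).
#' @export
lda_fit <- function(scores, labels, priors = c("proportional", "equal"),
                    n_components = "auto") {
  X <- score_matrix(scores)
  labels <- as.character(labels)
  if (length(labels) != nrow(X)) {
    stop("labels must match the number of rows", call. = FALSE)
  }
  groups <- sort(unique(labels))
  G <- length(groups)
  if (G < 2) stop("need at least 2 groups", call. = FALSE)
  sizes <- table(factor(labels, levels = groups))
  if (any(sizes < 2)) {
    stop(sprintf("group '%s' has fewer than 2 members",
                 groups[which(sizes < 2)[1]]), call. = FALSE)
  }
  n <- nrow(X)

  # retained-PC reduction
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  cap <- min(ncol(X), n - G - 1)
  if (identical(n_components, "auto")) {
    m <- min(sum(ev > 1e-10 * ev[1]), cap)
  } else {
    m <- as.integer(n_components)
    if (m < 1 || m > ncol(pc$rotation)) {
      stop("n_components out of range", call. = FALSE)
    }
  }
  rot <- pc$rotation[, seq_len(m), drop = FALSE]
  Z <- pc$x[, seq_len(m), drop = FALSE]

  if (is.character(priors)) {
    priors <- match.arg(priors, c("proportional", "equal"))
    pr <- if (priors == "proportional") as.numeric(sizes) / n
          else rep(1 / G, G)
  } else {
    pr <- as.numeric(priors[groups])
    if (anyNA(pr) || abs(sum(pr) - 1) > 1e-8) {
      stop("explicit priors must be named by group and sum to 1",
           call. = FALSE)
    }
  }
  names(pr) <- groups

  means <- t(vapply(groups, function(g) colMeans(Z[labels == g, , drop = FALSE]),
                    numeric(m)))
  Sw <- matrix(0, m, m)
  for (g in groups) {
    Zg <- Z[labels == g, , drop = FALSE]
    dev <- sweep(Zg, 2, colMeans(Zg))
    Sw <- Sw + crossprod(dev)
  }
  Sw <- Sw / (n - G)
  eig_w <- eigen(Sw, symmetric = TRUE)
  if (min(eig_w$values) <= 1e-12 * max(eig_w$values)) {
    stop(sprintf(
      "pooled within-group covariance is singular with %d retained components; refit with a smaller n_components",
      m), call. = FALSE)
  }
  Sw_inv <- eig_w$vectors %*% diag(1 / eig_w$values, m) %*% t(eig_w$vectors)
  W_half <- eig_w$vectors %*% diag(1 / sqrt(eig_w$values), m) %*% t(eig_w$vectors)

  grand <- colMeans(Z)
  Sb <- matrix(0, m, m)
  for (gi in seq_along(groups)) {
    d <- means[gi, ] - grand
    Sb <- Sb + sizes[gi] * tcrossprod(d)
  }
  Sb <- Sb / n
  eig_b <- eigen(W_half %*% Sb %*% W_half, symmetric = TRUE)
  n_axes <- min(G - 1, m)
  axes <- W_half %*% eig_b$vectors[, seq_len(n_axes), drop = FALSE]
  axes <- sweep(axes, 2, sqrt(colSums(axes^2)), "/")

  structure(list(
    groups = groups, priors = pr, sizes = as.integer(sizes),
    pc_center = pc$center, pc_rotation = rot, m = m,
    group_means = means, pooled_covariance = Sw,
    pooled_covariance_inv = Sw_inv,
    discriminant_axes = axes,
    discriminant_eigenvalues = eig_b$values[seq_len(n_axes)],
    labels = labels
  ), class = "shape_lda")
}

#' @export
print.shape_lda <- function(x, ...) {
  cat(sprintf(
    "Shape LDA: %d groups, %d retained components, %d discriminant axes\n",
    length(x$groups), x$m, ncol(x$discriminant_axes)))
  invisible(x)
}

#' Group means and sizes of a discriminant model
#' @param x a `shape_lda` object.
#' @param ... unused.
#' @export
tidy.shape_lda <- function(x, ...) {
  tibble::tibble(group = x$groups, n = x$sizes, prior = as.numeric(x$priors))
}

#' @export
glance.shape_lda <- function(x, ...) {
  tibble::tibble(n_groups = length(x$groups), retained_components = x$m,
                 n_discriminant_axes = ncol(x$discriminant_axes),
                 n = length(x$labels))
}

# Internal: map score rows into the model's reduced (retained-PC) space.
# space = "input" applies the model's centering + PC rotation; "reduced"
# asserts the rows are already in the retained-PC space.
reduce_rows <- function(model, rows, space = c("input", "reduced")) {
  space <- match.arg(space)
  if (is.numeric(rows) && is.null(dim(rows))) rows <- matrix(rows, nrow = 1)
  rows <- score_matrix(rows)
  if (space == "reduced") {
    if (ncol(rows) != model$m) {
      stop(sprintf("row dimension %d does not match reduced dimension %d",
                   ncol(rows), model$m), call. = FALSE)
    }
    return(rows)
  }
  if (ncol(rows) != length(model$pc_center)) {
    stop(sprintf("row dimension %d does not match model input dimension %d",
                 ncol(rows), length(model$pc_center)), call. = FALSE)
  }
  sweep(rows, 2, model$pc_center) %*% model$pc_rotation
}

#' Mahalanobis distance from a point to every group mean
#'
#' `MD_g = sqrt((z - mean_g)' Sigma^-1 (z - mean_g))` with the pooled
#' within-group covariance. Rows in the model's original input space are
#' passed through the retained-PC transform first; rows already of the
#' reduced dimension are used as-is.
#'
#' @param model a `shape_lda` object.
#' @param rows one or more score rows (vector or matrix).
#' @param space `"input"` (rows are in the model's original input space;
#'   default) or `"reduced"` (rows are already retained-PC scores).
#' @return a matrix (rows x groups) of non-negative distances.
#' @export
mahalanobis_to_groups <- function(model, rows, space = "input") {
  Z <- reduce_rows(model, rows, space = space)
  out <- vapply(seq_along(model$groups), function(gi) {
    sqrt(stats::mahalanobis(Z, model$group_means[gi, ],
                            model$pooled_covariance_inv, inverted = TRUE))
  }, numeric(nrow(Z)))
  out <- matrix(out, nrow = nrow(Z),
                dimnames = list(rownames(Z), model$groups))
  out
}

#' Posterior probabilities of group membership
#'
#' Under the shared-covariance Gaussian model,
#' `PP_g` is proportional to `prior_g * exp(-MD_g^2 / 2)`, normalized over
#' groups. The normalization uses a log-sum-exp guard so that extreme
#' distances never underflow to 0/0.
#'
#' @inheritParams mahalanobis_to_groups
#' @return a matrix (rows x groups) of probabilities; each row sums to 1.
#' @export
posterior_probabilities <- function(model, rows, space = "input") {
  md <- mahalanobis_to_groups(model, rows, space = space)
  lp <- sweep(-md^2 / 2, 2, log(model$priors), "+")
  mx <- apply(lp, 1, max)
  p <- exp(lp - mx)
  p / rowSums(p)
}

#' Classify score rows with a discriminant model
#'
#' Assigns each row to the group with the highest posterior probability.
#' Exact posterior ties are broken toward the first group in label order and
#' flagged.
#'
#' @param object a `shape_lda` object.
#' @param newdata score rows (original input space or reduced space).
#' @param ... unused.
#' @return a tibble with `predicted`, `tie_flag`, and the per-group posterior
#'   columns `PP_<group>`.
#' @export
predict.shape_lda <- function(object, newdata, ...) {
  pp <- posterior_probabilities(object, newdata)
  best <- apply(pp, 1, which.max)  # which.max takes the first on ties
  tie <- apply(pp, 1, function(r) sum(r == max(r)) > 1)
  out <- tibble::tibble(
    predicted = object$groups[best],
    tie_flag = tie
  )
  pp_tbl <- tibble::as_tibble(pp, .name_repair = "minimal")
  names(pp_tbl) <- paste0("PP_", object$groups)
  dplyr::bind_cols(out, pp_tbl)
}

#' Leave-one-out cross-validated classification
#'
#' For every specimen the discriminant model -- including its retained-PC
#' reduction -- is refit on the remaining n - 1 rows and the held-out row is
#' classified by highest posterior probability. Tallies go into a confusion
#' matrix (rows = true group, columns = predicted).
#'
#' @inheritParams lda_fit
#' @return an object of class `shape_confusion`; see [hit_ratios()].
#' @export
loo_crossvalidate <- function(scores, labels, priors = "proportional",
                              n_components = "auto") {
  X <- score_matrix(scores)
  labels <- as.character(labels)
  n <- nrow(X)
  groups <- sort(unique(labels))
  pred <- character(n)
  for (i in seq_len(n)) {
    fit <- lda_fit(X[-i, , drop = FALSE], labels[-i], priors = priors,
                   n_components = n_components)
    pred[i] <- predict(fit, X[i, , drop = FALSE])$predicted[1]
  }
  confusion_matrix(truth = labels, predicted = pred, groups = groups)
}

#' Build a confusion matrix from true and predicted labels
#'
#' @param truth,predicted character vectors of equal length.
#' @param groups optional ordered label set (defaults to the sorted union).
#' @return an object of class `shape_confusion` wrapping the G x G count
#'   matrix.
#' @export
confusion_matrix <- function(truth, predicted, groups = NULL) {
  if (is.null(groups)) groups <- sort(union(truth, predicted))
  counts <- table(factor(truth, levels = groups),
                  factor(predicted, levels = groups))
  counts <- matrix(as.integer(counts), nrow = length(groups),
                   dimnames = list(truth = groups, predicted = groups))
  structure(list(groups = groups, counts = counts), class = "shape_confusion")
}

#' Hit ratios of a confusion matrix
#'
#' Per-group hit ratio is `100 * diagonal / row sum` (conventionally
#' displayed rounded to the nearest integer); the overall hit ratio is
#' `100 * sum(diagonal) / n` (displayed at two decimals). Full precision is
#' kept in the returned columns; the `display` columns carry the rounded
#' form.
#'
#' @param confusion a `shape_confusion` object.
#' @return a list with `per_group` (tibble: group, n, n_correct, hit_ratio,
#'   hit_ratio_display), `overall_hit_ratio`, `overall_display`, and
#'   `n_misclassified`.
#' @export
hit_ratios <- function(confusion) {
  stopifnot(inherits(confusion, "shape_confusion"))
  counts <- confusion$counts
  rs <- rowSums(counts)
  if (any(rs == 0)) {
    warning("group(s) with no specimens: hit ratio undefined for ",
            paste(confusion$groups[rs == 0], collapse = ", "), call. = FALSE)
  }
  diagv <- unname(diag(counts))
  rs <- unname(rs)
  per <- tibble::tibble(
    group = confusion$groups,
    n = as.integer(rs),
    n_correct = as.integer(diagv),
    hit_ratio = ifelse(rs > 0, 100 * diagv / rs, NA_real_),
    hit_ratio_display = ifelse(rs > 0, round(100 * diagv / rs), NA_real_)
  )
  total <- sum(counts)
  overall <- 100 * sum(diagv) / total
  list(per_group = per,
       overall_hit_ratio = overall,
       overall_display = round(overall, 2),
       n_misclassified = as.integer(total - sum(diagv)))
}

#' @export
print.shape_confusion <- function(x, ...) {
  hr <- hit_ratios(x)
  cat(sprintf("Cross-validation confusion matrix (%d groups, n = %d)\n",
              length(x$groups), sum(x$counts)))
  cat(sprintf("  overall hit ratio: %.2f%% (%d misclassified)\n",
              hr$overall_hit_ratio, hr$n_misclassified))
  invisible(x)
}

#' Long-form counts of a confusion matrix
#' @param x a `shape_confusion` object.
#' @param ... unused.
#' @export
tidy.shape_confusion <- function(x, ...) {
  as.data.frame(as.table(x$counts), stringsAsFactors = FALSE) |>
    tibble::as_tibble() |>
    rlang::set_names(c("truth", "predicted", "count"))
}

#' @export
glance.shape_confusion <- function(x, ...) {
  hr <- hit_ratios(x)
  tibble::tibble(n = sum(x$counts),
                 overall_hit_ratio = hr$overall_hit_ratio,
                 n_misclassified = hr$n_misclassified)
}
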