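test_that("pca percent variance normalizes and degenerate data collapses to one axis", {
  set.seed(1)
  X <- matrix(rnorm(200), ncol = 4)
  p <- pca_fit(X)
  expect_equal(sum(p$percent_variance), 100, tolerance = 1e-9)
  expect_true(all(diff(p$eigenvalues) <= 1e-12))
  expect_equal(crossprod(p$axes), diag(ncol(p$axes)), tolerance = 1e-9,
               ignore_attr = TRUE)
  # collinear data: all variance on the first axis
  line <- cbind(1:50, 2 * (1:50) + 3)
  pl <- pca_fit(line)
  expect_equal(pl$percent_variance[1], 100, tolerance = 1e-9)
  expect_equal(pl$percent_variance[2], 0, tolerance = 1e-9)
})

test_that("full-rank pca scores preserve pairwise distances of centered data", {
  set.seed(2)
  X <- matrix(rnorm(30 * 5), ncol = 5)
  p <- pca_fit(X)
  expect_equal(as.vector(dist(p$scores)),
               as.vector(dist(scale(X, scale = FALSE))), tolerance = 1e-9)
})

test_that("lda separates well-separated 1-D groups and respects the axis bound", {
  set.seed(3)
  x <- c(rnorm(20, 0, 0.1), rnorm(20, 10, 0.1))
  X <- cbind(x, rnorm(40, sd = 0.1))
  labels <- rep(c("a", "b"), each = 20)
  fit <- lda_fit(X, labels)
  expect_equal(ncol(fit$discriminant_axes), 1L)
  pred <- predict(fit, X)
  expect_equal(pred$predicted, labels)
  expect_error(lda_fit(X, c("a", rep("b", 39))), "fewer than 2")
})

test_that("the auto reduction rescues rank-deficient tangent coordinates", {
  d <- simulate_dataset(wing_sim_spec(groups = c(A = 20L, B = 20L),
                                      effect_size = 0.05, noise_sd = 0.01,
                                      seed = 4))
  ts <- project_to_tangent(gpa(d))
  labels <- ts$meta$group
  # full 2k columns are rank deficient: forcing them all in must fail
  expect_error(lda_fit(ts$scores, labels, n_components = ncol(ts$scores)),
               "singular")
  fit <- lda_fit(ts$scores, labels)
  expect_lte(fit$m, 2 * 18 - 4)
  expect_lte(ncol(fit$discriminant_axes), length(fit$groups) - 1)
  expect_equal(sum(fit$priors), 1, tolerance = 1e-12)
})

test_that("mahalanobis distances match closed forms", {
  # hand-built two-group model in a 2-D reduced space
  model <- structure(list(
    groups = c("g1", "g2"),
    priors = c(g1 = 0.5, g2 = 0.5),
    m = 2L,
    pc_center = c(0, 0), pc_rotation = diag(2),
    group_means = rbind(c(0, 0), c(5, 5)),
    pooled_covariance = diag(c(1, 4)),
    pooled_covariance_inv = diag(c(1, 1 / 4))
  ), class = "shape_lda")
  md <- mahalanobis_to_groups(model, c(1, 2), space = "reduced")
  expect_equal(unname(md[1, "g1"]), sqrt(1 + 4 / 4), tolerance = 1e-12)
  expect_equal(unname(md[1, "g2"]), sqrt(16 / 1 + 9 / 4), tolerance = 1e-12)
  # at a group mean the distance to that group is zero
  md0 <- mahalanobis_to_groups(model, c(0, 0), space = "reduced")
  expect_equal(unname(md0[1, "g1"]), 0)
  # identity covariance: Mahalanobis reduces to Euclidean
  model$pooled_covariance_inv <- diag(2)
  mde <- mahalanobis_to_groups(model, c(3, 4), space = "reduced")
  expect_equal(unname(mde[1, "g1"]), 5, tolerance = 1e-12)
  expect_error(mahalanobis_to_groups(model, c(1, 2, 3), space = "reduced"),
               "dimension")
})

test_that("posterior probabilities follow the Gaussian closed form and never underflow", {
  model <- structure(list(
    groups = c("g1", "g2"),
    priors = c(g1 = 0.5, g2 = 0.5),
    m = 1L,
    pc_center = 0, pc_rotation = matrix(1),
    group_means = rbind(0, 2),
    pooled_covariance = matrix(1),
    pooled_covariance_inv = matrix(1)
  ), class = "shape_lda")
  # midway between unit-variance means: symmetric posteriors
  pp_mid <- posterior_probabilities(model, 1, space = "reduced")
  expect_equal(as.vector(pp_mid), c(0.5, 0.5), tolerance = 1e-12)
  # at the first mean: ratio of normal densities exp(2)/(1+exp(2))
  pp0 <- posterior_probabilities(model, 0, space = "reduced")
  expect_equal(unname(pp0[1, "g1"]), exp(2) / (1 + exp(2)),
               tolerance = 1e-12)
  # extreme distances: still a valid probability vector (log-sum-exp guard)
  pp_far <- posterior_probabilities(model, 1e4, space = "reduced")
  expect_equal(sum(pp_far), 1, tolerance = 1e-12)
  expect_false(anyNA(pp_far))
})

test_that("posteriors sum to 1 and equal-prior assignment matches minimum distance", {
  set.seed(5)
  d <- tiny_dataset(c(A = 8, B = 8, C = 8), noise = 0.05)
  ts <- project_to_tangent(gpa(d))
  fit <- lda_fit(ts$scores, ts$meta$group, priors = "equal",
                 n_components = 4)
  pp <- posterior_probabilities(fit, ts$scores)
  expect_equal(rowSums(pp), rep(1, nrow(pp)), tolerance = 1e-12,
               ignore_attr = TRUE)
  md <- mahalanobis_to_groups(fit, ts$scores)
  expect_equal(apply(pp, 1, which.max), apply(md, 1, which.min),
               ignore_attr = TRUE)
})

test_that("classification agrees with an independent reference implementation", {
  skip_if_not_installed("MASS")
  set.seed(6)
  for (trial in 1:5) {
    n <- sample(30:100, 1)
    p <- sample(2:5, 1)
    G <- sample(2:4, 1)
    labels <- sample(letters[1:G], n, replace = TRUE)
    while (min(table(labels)) < p + 2) {
      labels <- sample(letters[1:G], n, replace = TRUE)
    }
    means <- matrix(rnorm(G * p, sd = 3), nrow = G,
                    dimnames = list(letters[1:G], NULL))
    X <- means[labels, ] + matrix(rnorm(n * p), ncol = p)
    ours <- lda_fit(X, labels, priors = "proportional", n_components = p)
    ref <- MASS::lda(X, grouping = labels)
    expect_equal(predict(ours, X)$predicted,
                 as.character(predict(ref, X)$class))
  }
})

test_that("optimal rotation agrees with an independent Procrustes implementation", {
  skip_if_not_installed("vegan")
  set.seed(7)
  a <- to_preshape(random_config(10))
  b <- to_preshape(a %*% rot2(0.7) +
                     matrix(rnorm(20, sd = 0.02), ncol = 2))
  ours <- optimal_rotation(a, b)
  ref <- vegan::procrustes(b, a, scale = FALSE, symmetric = FALSE)
  expect_equal(ours, ref$rotation, tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("loo cross-validation is perfect for separable groups and row sums match", {
  set.seed(8)
  d <- tiny_dataset(c(A = 10, B = 10), noise = 0.005, offset = 0.4)
  ts <- project_to_tangent(gpa(d))
  conf <- loo_crossvalidate(ts, ts$meta$group, n_components = 4)
  hr <- hit_ratios(conf)
  expect_equal(hr$overall_hit_ratio, 100)
  expect_equal(rowSums(conf$counts), c(A = 10, B = 10), ignore_attr = TRUE)
})

test_that("loo cross-validation is at chance for permuted labels", {
  set.seed(9)
  n <- 200
  X <- matrix(rnorm(n * 4), ncol = 4)
  labels <- sample(rep(letters[1:4], each = n / 4))
  conf <- loo_crossvalidate(X, labels, n_components = 4)
  hr <- hit_ratios(conf)
  expect_lt(abs(hr$overall_hit_ratio - 25), 5)
  expect_equal(sum(conf$counts), n)
})

test_that("hit ratio accuracy rises with group separation", {
  set.seed(10)
  overall <- vapply(c(0, 0.5, 2), function(sep) {
    X <- rbind(matrix(rnorm(40 * 2), ncol = 2),
               matrix(rnorm(40 * 2, mean = sep), ncol = 2))
    labels <- rep(c("a", "b"), each = 40)
    hit_ratios(loo_crossvalidate(X, labels, n_components = 2))$overall_hit_ratio
  }, numeric(1))
  expect_true(all(diff(overall) > -5))  # monotone within simulation noise
  expect_gt(overall[3], overall[1])
})

test_that("hit ratios and misclassification counts follow the counting rules", {
  conf <- confusion_matrix(truth = c("a", "a", "a", "b", "b"),
                           predicted = c("a", "a", "b", "b", "b"))
  hr <- hit_ratios(conf)
  expect_equal(hr$per_group$hit_ratio, c(100 * 2 / 3, 100))
  expect_equal(hr$per_group$hit_ratio_display, c(67, 100))
  expect_equal(hr$overall_hit_ratio, 80)
  expect_equal(hr$n_misclassified, 1L)
  # identity counts: all 100%
  ident <- confusion_matrix(truth = rep(letters[1:3], 4),
                            predicted = rep(letters[1:3], 4))
  expect_true(all(hit_ratios(ident)$per_group$hit_ratio == 100))
})
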