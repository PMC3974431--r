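test_that("centroid size matches closed forms and a brute-force summation oracle", {
  sq <- cbind(c(-0.5, 0.5, 0.5, -0.5), c(-0.5, -0.5, 0.5, 0.5))
  expect_equal(centroid_size(sq), sqrt(2), tolerance = 1e-12)
  set.seed(1)
  m <- random_config(18)
  expect_equal(centroid_size(3 * m), 3 * centroid_size(m), tolerance = 1e-12)
  # independent elementwise summation
  cx <- mean(m[, 1]); cy <- mean(m[, 2])
  acc <- 0
  for (i in seq_len(nrow(m))) {
    acc <- acc + (m[i, 1] - cx)^2 + (m[i, 2] - cy)^2
  }
  expect_equal(centroid_size(m), sqrt(acc), tolerance = 1e-12)
  expect_error(centroid_size(matrix(1, 4, 2)), "degenerate")
})

test_that("preshapes are centered, unit-size, and invariant to translation", {
  set.seed(2)
  m <- random_config(12)
  p <- to_preshape(m)
  expect_lt(max(abs(colMeans(p))), 1e-9)
  expect_equal(centroid_size(p), 1, tolerance = 1e-9)
  expect_equal(to_preshape(p), p, tolerance = 1e-12)                # idempotent
  expect_equal(to_preshape(sweep(m, 2, c(4, -7), "+")), p,
               tolerance = 1e-12)                                   # translation
  expect_error(to_preshape(matrix(2, 5, 2)), "degenerate")
})

test_that("optimal_rotation recovers exact angles and is a proper rotation", {
  set.seed(3)
  p <- to_preshape(random_config(10))
  r0 <- optimal_rotation(p, p)
  expect_equal(r0, diag(2), tolerance = 1e-9)
  src <- p %*% rot2(pi / 6)
  r <- optimal_rotation(src, p)
  expect_equal(det(r), 1, tolerance = 1e-12)
  expect_equal(rotation_angle(r), -pi / 6, tolerance = 1e-9)
})

test_that("optimal_rotation and procrustes_distance match the grid-search oracle", {
  set.seed(4)
  for (i in 1:100) {
    a <- to_preshape(random_config(8))
    b <- to_preshape(a + matrix(rnorm(16, sd = 0.3), ncol = 2))
    oracle <- grid_rotation_oracle(a, b, step = 1e-4)
    r <- optimal_rotation(a, b)
    expect_lt(abs(rotation_angle(r) - oracle$angle), 1e-3)
    expect_lt(abs(procrustes_distance(a, b, "partial") - oracle$distance),
              1e-4)
  }
  # and against the fully direct (residual-norm) oracle on a few pairs
  set.seed(5)
  for (i in 1:5) {
    a <- to_preshape(random_config(6))
    b <- to_preshape(random_config(6))
    oracle <- grid_rotation_oracle_direct(a, b, step = 1e-4)
    expect_lt(abs(procrustes_distance(a, b, "partial") - oracle$distance),
              1e-4)
  }
})

test_that("procrustes distances vanish on similarity-transformed copies and are symmetric", {
  set.seed(6)
  m <- random_config(9)
  # identical shapes: distances at the numerical floor (sqrt/acos near 1
  # amplify machine epsilon to ~1e-8)
  expect_lt(procrustes_distance(m, m, "partial"), 1e-7)
  expect_lt(procrustes_distance(m, m, "rho"), 1e-7)
  t <- random_similarity(m)
  expect_lt(procrustes_distance(m, t, "partial"), 1e-7)
  expect_lt(procrustes_distance(m, t, "rho"), 1e-7)
  a <- random_config(9); b <- random_config(9)
  expect_equal(procrustes_distance(a, b, "rho"),
               procrustes_distance(b, a, "rho"), tolerance = 1e-12)
  expect_error(procrustes_distance(random_config(5), random_config(6)),
               "landmark counts")
})

test_that("rho satisfies the triangle inequality on random preshape triples", {
  set.seed(7)
  for (i in 1:25) {
    a <- random_config(7); b <- random_config(7); c <- random_config(7)
    dab <- procrustes_distance(a, b, "rho")
    dbc <- procrustes_distance(b, c, "rho")
    dac <- procrustes_distance(a, c, "rho")
    expect_lte(dac, dab + dbc + 1e-12)
  }
})

test_that("gpa collapses similarity-transformed copies onto one shape", {
  set.seed(8)
  m <- random_config(12)
  d <- dplyr::bind_rows(lapply(1:10, function(i) {
    landmark_data(random_similarity(m), sprintf("s%02d", i), group = "A")
  }))
  fit <- gpa(d)
  expect_true(fit$converged)
  for (i in 2:10) {
    expect_lt(sqrt(sum((fit$aligned[, , i] - fit$aligned[, , 1])^2)), 1e-9)
  }
  expect_lt(procrustes_distance(fit$consensus, m, "rho"), 1e-9)
  expect_error(gpa(landmark_data(m, "only_one")), "at least 2")
})

test_that("two-shape gpa places the consensus equidistant from both shapes", {
  set.seed(9)
  a <- random_config(10)
  b <- a + matrix(rnorm(20, sd = 0.2), ncol = 2)
  d <- dplyr::bind_rows(landmark_data(a, "a"), landmark_data(b, "b"))
  fit <- gpa(d)
  da <- procrustes_distance(fit$consensus, a, "rho")
  db <- procrustes_distance(fit$consensus, b, "rho")
  expect_equal(da, db, tolerance = 1e-6)
})

test_that("the gpa objective is non-increasing and output is order-stable up to gauge", {
  set.seed(10)
  d <- tiny_dataset(c(A = 8, B = 8), noise = 0.05)
  fit <- gpa(d)
  expect_true(all(diff(fit$ss_trace) <= 1e-12))
  # permuted input order: same consensus shape (gauge fixed by principal axis)
  ids <- unique(d$specimen_id)
  d2 <- d |> dplyr::arrange(match(specimen_id, rev(ids)), landmark)
  fit2 <- gpa(d2)
  expect_lt(procrustes_distance(fit$consensus, fit2$consensus, "rho"), 1e-6)
})

test_that("superimposition output is invariant to similarity transforms of inputs", {
  set.seed(11)
  d <- tiny_dataset(c(A = 6, B = 6), noise = 0.03)
  fit <- gpa(d)
  # transform one input arbitrarily; its aligned coordinates must not change
  d2 <- d
  pick <- unique(d$specimen_id)[3]
  sel <- d2$specimen_id == pick
  m <- cbind(d2$x[sel], d2$y[sel])
  t <- random_similarity(m)
  d2$x[sel] <- t[, 1]; d2$y[sel] <- t[, 2]
  fit2 <- gpa(d2)
  expect_equal(fit2$aligned, fit$aligned, tolerance = 1e-9)
})

test_that("tangent projection sends the consensus to the origin and obeys the rank bound", {
  set.seed(12)
  d <- tiny_dataset(c(A = 10, B = 10), noise = 0.02, k = 8)
  fit <- gpa(d)
  ts <- project_to_tangent(fit)
  expect_equal(ts$rank_bound, 2L * 8L - 4L)
  sv <- svd(ts$scores)$d
  expect_lte(sum(sv > 1e-9 * sv[1]), ts$rank_bound)
  # project the consensus itself (as one more specimen) -> zero row
  d2 <- dplyr::bind_rows(d, landmark_data(fit$consensus, "consensus_row"))
  fit2 <- gpa(d2)
  ts2 <- project_to_tangent(fit2)
  # the consensus of d2 differs slightly from fit$consensus; instead check
  # algebraically: a row equal to the tangent point maps to the origin
  cvec <- as.vector(t(fit$consensus))
  lam <- sum(cvec * cvec)
  projected <- (cvec - (lam - 1) * cvec) - cvec
  expect_lt(max(abs(projected)), 1e-12)
  expect_true(is.matrix(ts2$scores))
})

test_that("tangent distances match rho distances in the small-variation limit", {
  spec <- wing_sim_spec(groups = c(A = 100L), effect_size = 0,
                        noise_sd = 0.01, seed = 21)
  d <- simulate_dataset(spec)
  fit <- gpa(d)
  ts <- project_to_tangent(fit)
  euc <- as.vector(dist(ts$scores))
  rho <- wingshape:::pairwise_rho(fit$aligned)
  ratio <- euc / rho
  expect_true(all(ratio > 0.999 & ratio < 1.001))
})

test_that("tangent adequacy is near 1 at low variance and degrades monotonically", {
  low <- simulate_dataset(wing_sim_spec(groups = c(A = 100L), effect_size = 0,
                                        noise_sd = 0.01, seed = 22))
  high <- simulate_dataset(wing_sim_spec(groups = c(A = 100L), effect_size = 0,
                                         noise_sd = 0.30, seed = 22))
  rep_low <- tangent_adequacy(gpa(low))
  rep_high <- tangent_adequacy(gpa(high))
  expect_equal(rep_low$n_pairs, 100 * 99 / 2)
  expect_gte(rep_low$slope, 0.999)
  expect_gte(rep_low$correlation, 0.999)
  expect_lt(rep_high$slope, rep_low$slope)
  expect_true(rep_low$correlation <= 1 + 1e-12)
})

test_that("adequacy errors on a sample with no shape variation", {
  m <- random_config(8)
  d <- dplyr::bind_rows(lapply(1:5, function(i) {
    landmark_data(random_similarity(m), sprintf("s%d", i))
  }))
  expect_error(tangent_adequacy(gpa(d)), "no shape variation")
})
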