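#' Specification for a synthetic wing-landmark dataset
#'
#' Describes the statistical structure the assignment pipeline assumes:
#' a common template shape, group-distinct mean-shape displacements of a
#' controlled magnitude, isotropic per-landmark Gaussian noise, arbitrary
#' similarity-transform nuisance (position, rotation, scale), and a separate
#' replicate-digitization error level. All magnitudes are in units of the
#' template's centroid size (which is 1).
#'
#' The default group structure mirrors a curated bee-forewing reference
#' collection: 360 specimens in 15 subfamily-like groups with sizes ranging
#' from 5 to 117.
#'
#' @param k landmarks per configuration.
#' @param groups named integer vector: specimens per group.
#' @param effect_size norm of each group's mean-shape displacement (pure
#'   shape signal: displacements are orthogonalized against similarity
#'   transforms of the template).
#' @param noise_sd per-landmark per-axis shape noise sd; may be a length-k
#'   vector for heteroscedastic experiments.
#' @param digitization_sd per-landmark per-axis replicate digitization sd.
#' @param rotation_range,translation_range,log_scale_range nuisance ranges
#'   (uniform) for the similarity transform applied to every simulated
#'   configuration.
#' @param seed integer seed; the same spec and seed give identical data.
#'   Group-level draws use independent sub-streams so adding a group does
#'   not perturb earlier groups.
#' @return a list of class `wing_sim_spec`.
#' @export
wing_sim_spec <- function(k = 18,
                          groups = reference_group_sizes(),
                          effect_size = 0.05,
                          noise_sd = 0.01,
                          digitization_sd = 0.005,
                          rotation_range = c(-pi, pi),
                          translation_range = c(-2, 2),
                          log_scale_range = c(-0.7, 0.7),
                          seed = 1L) {
  stopifnot(k >= 3, length(groups) >= 1, all(groups >= 1),
            effect_size >= 0, all(noise_sd >= 0), digitization_sd >= 0)
  if (is.null(names(groups)) || any(names(groups) == "")) {
    names(groups) <- sprintf("group%02d", seq_along(groups))
  }
  structure(list(
    k = as.integer(k), groups = groups,
    effect_size = effect_size, noise_sd = noise_sd,
    digitization_sd = digitization_sd,
    rotation_range = rotation_range,
    translation_range = translation_range,
    log_scale_range = log_scale_range,
    seed = as.integer(seed)
  ), class = "wing_sim_spec")
}

#' Group sizes of the default reference design
#'
#' Fifteen subfamily-level groups totalling 360 specimens, matching the
#' composition of the curated bee-forewing reference collection shipped in
#' `inst/extdata/bee_subfamily_composition.csv`.
#'
#' @return a named integer vector.
#' @export
reference_group_sizes <- function() {
  c(Andreninae = 20L, Apinae = 34L, Colletinae = 20L, Diphaglossinae = 20L,
    Fideliinae = 13L, Halictinae = 25L, Meganomiinae = 7L, Melittinae = 117L,
    Nomadinae = 20L, Nomiinae = 20L, Nomioidinae = 11L, Oxaeinae = 5L,
    Panurginae = 11L, Rophitinae = 17L, Xylocopinae = 20L)
}

# Internal: derived sub-stream seed, kept under 2^31.
substream_seed <- function(seed, stream) {
  as.integer((as.double(seed) * 48271 + stream * 7919) %% 2147483647)
}

#' Deterministic template wing shape
#'
#' Places k landmarks on a flattened convex arc (an ellipse-like outline,
#' emulating a wing's vein-intersection spread) perturbed by seeded jitter,
#' centered and scaled to unit centroid size. The same `(k, seed)` always
#' yields identical coordinates.
#'
#' @param k number of landmarks (>= 3).
#' @param seed integer seed for the jitter.
#' @return a k x 2 coordinate matrix with centroid 0 and centroid size 1.
#' @export
make_template <- function(k = 18, seed = 1L) {
  if (k < 3) stop("template needs at least 3 landmarks", call. = FALSE)
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old))
  set.seed(substream_seed(seed, 0L))
  theta <- seq(0, 2 * pi, length.out = k + 1)[seq_len(k)]
  base <- cbind(cos(theta), 0.45 * sin(theta))
  jitter <- matrix(stats::runif(2 * k, -0.08, 0.08), ncol = 2)
  to_preshape(base + jitter)
}

# Internal: save/restore the global RNG state so simulation functions do not
# disturb the caller's stream.
.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_set <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

# Internal: orthonormal basis of the similarity-transform directions at a
# template (x-translation, y-translation, scaling, infinitesimal rotation),
# as columns of a 2k x 4 matrix in (x1, y1, ...) vectorization.
similarity_basis <- function(template) {
  k <- nrow(template)
  tx <- vec_config(cbind(rep(1, k), rep(0, k)))
  ty <- vec_config(cbind(rep(0, k), rep(1, k)))
  sc <- vec_config(template)
  ro <- vec_config(cbind(-template[, 2], template[, 1]))
  qr.Q(qr(cbind(tx, ty, sc, ro)))
}

# Internal: group mean shapes = template + seeded displacement fields of norm
# effect_size, orthogonal to the template's similarity directions.
group_mean_shapes <- function(spec, template) {
  basis <- similarity_basis(template)
  tvec <- vec_config(template)
  means <- vector("list", length(spec$groups))
  names(means) <- names(spec$groups)
  for (gi in seq_along(spec$groups)) {
    set.seed(substream_seed(spec$seed, gi))
    d <- stats::rnorm(2 * spec$k)
    d <- d - basis %*% crossprod(basis, d)  # pure shape direction
    if (spec$effect_size > 0) {
      d <- d / sqrt(sum(d^2)) * spec$effect_size
    } else {
      d <- d * 0
    }
    means[[gi]] <- unvec_config(tvec + d)
  }
  means
}

# Internal: apply isotropic noise + a random similarity transform to a mean
# shape, using the current RNG stream.
perturb_config <- function(mean_shape, noise_sd, spec) {
  k <- nrow(mean_shape)
  noise <- matrix(stats::rnorm(2 * k, sd = noise_sd), ncol = 2)
  m <- mean_shape + noise
  ang <- stats::runif(1, spec$rotation_range[1], spec$rotation_range[2])
  sc <- exp(stats::runif(1, spec$log_scale_range[1], spec$log_scale_range[2]))
  tr <- stats::runif(2, spec$translation_range[1], spec$translation_range[2])
  rot <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2)
  sweep(sc * m %*% rot, 2, tr, "+")
}

#' Simulate a labeled landmark dataset
#'
#' Draws, for each group in the spec, a mean shape (template plus a seeded
#' pure-shape displacement of norm `effect_size`), then each specimen as the
#' group mean plus i.i.d. Gaussian landmark noise followed by a random
#' similarity transform from the nuisance ranges. Fully deterministic given
#' the spec (including its seed); each group uses an independent sub-stream.
#'
#' @param spec a [wing_sim_spec()].
#' @return a labeled landmark tibble (specimen ids `<group>_<i>`, side
#'   `"right"`).
#' @export
simulate_dataset <- function(spec) {
  stopifnot(inherits(spec, "wing_sim_spec"))
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old))
  template <- make_template(spec$k, spec$seed)
  means <- group_mean_shapes(spec, template)
  out <- vector("list", sum(spec$groups))
  idx <- 0L
  for (gi in seq_along(spec$groups)) {
    g <- names(spec$groups)[gi]
    set.seed(substream_seed(spec$seed, 10000L + gi))
    for (i in seq_len(spec$groups[[gi]])) {
      idx <- idx + 1L
      m <- perturb_config(means[[g]], spec$noise_sd, spec)
      out[[idx]] <- landmark_data(m, sprintf("%s_%03d", g, i),
                                  side = "right", group = g)
    }
  }
  dplyr::bind_rows(out)
}

#' Simulate replicate digitizations of one unknown specimen
#'
#' Draws one true underlying specimen from a group's model (group mean plus
#' shape noise), then produces `n_replicates` observed configurations of it,
#' each with independent digitization noise (`digitization_sd`) and an
#' independent nuisance similarity transform -- emulating the same wing being
#' digitized several times by different experimenters.
#'
#' @param spec a [wing_sim_spec()].
#' @param group_label group to draw the true specimen from.
#' @param n_replicates number of replicate digitizations.
#' @param id_prefix prefix for replicate specimen ids.
#' @param stream extra offset for the sub-stream seed so multiple unknowns
#'   can be drawn independently.
#' @return a landmark tibble of `n_replicates` configurations with `group`
#'   set to `NA` (they are unknowns).
#' @export
simulate_replicates <- function(spec, group_label, n_replicates = 8,
                                id_prefix = "unknown", stream = 0L) {
  stopifnot(inherits(spec, "wing_sim_spec"))
  gi <- match(group_label, names(spec$groups))
  if (is.na(gi)) {
    stop(sprintf("unknown group '%s'", group_label), call. = FALSE)
  }
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old))
  template <- make_template(spec$k, spec$seed)
  means <- group_mean_shapes(spec, template)
  set.seed(substream_seed(spec$seed, 20000L + gi + 997L * stream))
  true_specimen <- means[[gi]] +
    matrix(stats::rnorm(2 * spec$k, sd = spec$noise_sd), ncol = 2)
  out <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    m <- perturb_config(true_specimen, spec$digitization_sd, spec)
    out[[r]] <- landmark_data(m, sprintf("%s_rep%02d", id_prefix, r),
                              side = "right")
  }
  dplyr::bind_rows(out)
}
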