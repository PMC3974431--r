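#' Assign unknown configurations to reference groups
#'
#' The taxonomic-placement workflow for fossils and other unlabeled
#' specimens. In the default `mode = "joint"` the reference and unknown
#' configurations are superimposed together in one generalized Procrustes
#' fit; the discriminant model (retained-PC reduction, group means, pooled
#' covariance) is then estimated from the reference rows only, and the
#' unknown rows are passed a posteriori through the identical centering, PC
#' and discriminant maps. Each unknown receives a Mahalanobis distance and a
#' posterior probability per reference group and is assigned to the group
#' with the highest posterior. In `mode = "opa"` (for sensitivity analysis)
#' the reference is superimposed alone and each unknown is aligned one-by-one
#' onto the reference consensus, so unknowns cannot influence the consensus.
#'
#' Replicate digitizations of one physical specimen can be declared with
#' `replicate_map` (a tibble `specimen_id, unknown_id`); replicates are kept
#' as independent rows and additionally summarized by modal vote. When the
#' smallest Mahalanobis distance of an unknown exceeds the 99th percentile of
#' the reference's own within-group distances a warning flags a possible
#' "none of the above".
#'
#' @param reference a labeled landmark tibble (non-missing `group`).
#' @param unknowns a landmark tibble of configurations to place (same k).
#' @param priors,n_components passed to [lda_fit()].
#' @param mode `"joint"` (default) or `"opa"`.
#' @param replicate_map optional tibble with columns `specimen_id`,
#'   `unknown_id` mapping replicate digitizations to physical specimens;
#'   default: each unknown specimen is its own physical specimen.
#' @return an object of class `assignment_report` with `replicates` (tibble:
#'   one row per unknown replicate with `unknown_id`, `replicate_id`,
#'   `assigned_group`, `tie_flag`, `novelty_flag`, `min_md`, and `MD_<group>`
#'   / `PP_<group>` columns), `specimens` (modal summary per physical
#'   specimen), the fitted `lda`, and the run options.
#' @export
assign_unknowns <- function(reference, unknowns,
                            priors = "proportional", n_components = "auto",
                            mode = c("joint", "opa"),
                            replicate_map = NULL) {
  mode <- match.arg(mode)
  validate_landmarks(reference)
  validate_landmarks(unknowns)
  if (!"group" %in% names(reference) || anyNA(reference$group)) {
    stop("reference dataset must be fully labeled (column 'group')",
         call. = FALSE)
  }
  k_ref <- landmark_count(reference)
  k_unk <- landmark_count(unknowns)
  if (k_ref != k_unk) {
    stop(sprintf("landmark count mismatch: reference has k=%d, unknowns k=%d",
                 k_ref, k_unk), call. = FALSE)
  }
  ref_ids <- unique(reference$specimen_id)
  unk_ids <- unique(unknowns$specimen_id)
  if (length(intersect(ref_ids, unk_ids)) > 0) {
    unknowns <- dplyr::mutate(
      unknowns, specimen_id = paste0("unknown:", .data$specimen_id))
    unk_ids <- unique(unknowns$specimen_id)
    if (!is.null(replicate_map)) {
      replicate_map$specimen_id <- paste0("unknown:", replicate_map$specimen_id)
    }
  }

  if (mode == "joint") {
    unk <- unknowns
    unk$group <- NA_character_
    combined <- dplyr::bind_rows(
      reference[, intersect(names(reference),
                            c("specimen_id", "group", "side", "landmark",
                              "x", "y"))],
      unk[, intersect(names(unk),
                      c("specimen_id", "group", "side", "landmark",
                        "x", "y"))])
    fit <- gpa(combined)
    ts <- project_to_tangent(fit)
    is_ref <- ts$meta$specimen_id %in% ref_ids
    ref_scores <- ts$scores[is_ref, , drop = FALSE]
    unk_scores <- ts$scores[!is_ref, , drop = FALSE]
    labels <- ts$meta$group[is_ref]
  } else {
    fit <- gpa(reference)
    ts <- project_to_tangent(fit)
    ref_scores <- ts$scores
    labels <- ts$meta$group
    unk_scores <- opa_project(unknowns, fit)
  }

  model <- lda_fit(ref_scores, labels, priors = priors,
                   n_components = n_components)
  md <- mahalanobis_to_groups(model, unk_scores)
  pp <- posterior_probabilities(model, unk_scores)
  pred <- predict(model, unk_scores)

  # novelty threshold: 99th percentile of reference within-group MDs
  ref_md <- mahalanobis_to_groups(model, ref_scores)
  own_md <- ref_md[cbind(seq_along(labels), match(labels, model$groups))]
  novelty_cut <- stats::quantile(own_md, 0.99, names = FALSE)
  min_md <- apply(md, 1, min)

  if (is.null(replicate_map)) {
    replicate_map <- tibble::tibble(specimen_id = unk_ids,
                                    unknown_id = unk_ids)
  }
  rep_tbl <- tibble::tibble(
    replicate_id = rownames(unk_scores),
    assigned_group = pred$predicted,
    tie_flag = pred$tie_flag,
    min_md = min_md,
    novelty_flag = min_md > novelty_cut
  ) |>
    dplyr::left_join(replicate_map,
                     by = c(replicate_id = "specimen_id")) |>
    dplyr::mutate(unknown_id = dplyr::coalesce(.data$unknown_id,
                                               .data$replicate_id)) |>
    dplyr::relocate("unknown_id")
  md_tbl <- tibble::as_tibble(md, .name_repair = "minimal")
  names(md_tbl) <- paste0("MD_", model$groups)
  pp_tbl <- tibble::as_tibble(pp, .name_repair = "minimal")
  names(pp_tbl) <- paste0("PP_", model$groups)
  rep_tbl <- dplyr::bind_cols(rep_tbl, md_tbl, pp_tbl)

  if (any(rep_tbl$novelty_flag)) {
    warning(sprintf(
      "%d unknown replicate(s) have minimum Mahalanobis distance beyond the 99th percentile of reference within-group distances; the true group may be absent from the reference",
      sum(rep_tbl$novelty_flag)), call. = FALSE)
  }

  specimens <- rep_tbl |>
    dplyr::group_by(.data$unknown_id) |>
    dplyr::summarise(
      n_replicates = dplyr::n(),
      consensus_group = modal_label(.data$assigned_group),
      modal_agreement = mean(.data$assigned_group ==
                               modal_label(.data$assigned_group)),
      min_md = min(.data$min_md),
      max_pp = max(apply(
        dplyr::pick(dplyr::starts_with("PP_")), 1, max)),
      .groups = "drop")

  structure(list(
    replicates = rep_tbl,
    specimens = specimens,
    lda = model,
    gpa = fit,
    options = list(mode = mode, priors = priors,
                   n_components_rule = n_components,
                   retained_components = model$m,
                   novelty_cutoff = novelty_cut)
  ), class = "assignment_report")
}

# Internal: most frequent label; ties toward first in sorted order.
modal_label <- function(x) {
  tab <- sort(table(x), decreasing = TRUE)
  names(tab)[1]
}

# Internal: align unknowns one-by-one onto a fixed reference consensus
# (ordinary Procrustes) and express them as tangent scores of that fit.
opa_project <- function(unknowns, fit) {
  sp <- lm_split(unknowns)
  cvec <- vec_config(fit$consensus)
  out <- matrix(NA_real_, nrow = length(sp$ids), ncol = 2 * sp$k,
                dimnames = list(sp$ids, NULL))
  for (i in seq_along(sp$ids)) {
    p <- to_preshape(sp$coords[, , i])
    r <- optimal_rotation(p, fit$consensus)
    x <- vec_config(p %*% r)
    lam <- sum(x * cvec)
    out[i, ] <- (x - (lam - 1) * cvec) - cvec
  }
  out
}

#' @export
print.assignment_report <- function(x, ...) {
  cat(sprintf(
    "Assignment report: %d unknown replicate(s), %d physical specimen(s)\n",
    nrow(x$replicates), nrow(x$specimens)))
  cat(sprintf("  mode=%s, priors=%s, retained components=%d\n",
              x$options$mode, paste(x$options$priors, collapse = ","),
              x$options$retained_components))
  print(x$specimens)
  invisible(x)
}

#' Per-replicate assignment records
#' @param x an `assignment_report`.
#' @param ... unused.
#' @export
tidy.assignment_report <- function(x, ...) x$replicates

#' Per-specimen modal summary
#' @param x an `assignment_report`.
#' @param ... unused.
#' @export
glance.assignment_report <- function(x, ...) x$specimens

#' Write an assignment report to CSV
#'
#' Writes the per-replicate table (`unknown_id, replicate_id,
#' assigned_group, tie_flag`, then `MD_<group>` and `PP_<group>` columns) and
#' a companion per-specimen modal summary.
#'
#' @param report an `assignment_report`.
#' @param path output CSV path for the replicate table.
#' @param summary_path optional path for the per-specimen summary (default:
#'   `path` with `_summary` inserted before the extension).
#' @return `path`, invisibly.
#' @export
write_assignment_csv <- function(report, path, summary_path = NULL) {
  stopifnot(inherits(report, "assignment_report"))
  cols <- c("unknown_id", "replicate_id", "assigned_group", "tie_flag",
            grep("^MD_", names(report$replicates), value = TRUE),
            grep("^PP_", names(report$replicates), value = TRUE))
  readr::write_csv(report$replicates[, cols], path)
  if (is.null(summary_path)) {
    summary_path <- sub("(\\.[^.]*)?$", "_summary\\1", path)
  }
  readr::write_csv(report$specimens, summary_path)
  invisible(path)
}

#' PCA of a restricted reference with a-posteriori unknowns
#'
#' Superimposes the reference restricted to chosen groups together with the
#' unknowns, fits the PCA on the restricted reference rows only, and projects
#' the unknowns into that ordination -- the standard visualization for asking
#' whether an unknown falls inside a candidate clade's shape variation.
#'
#' @param reference labeled landmark tibble.
#' @param unknowns landmark tibble of unknowns (same k); may be `NULL`.
#' @param groups character vector of group labels to keep (default: all).
#' @return a list of class `subspace_pca` with `pca` (a `shape_pca` fitted on
#'   the restricted reference), `reference_scores` (tibble with group
#'   labels), and `unknown_scores` (tibble; empty when no unknowns).
#' @export
restricted_shape_pca <- function(reference, unknowns = NULL, groups = NULL) {
  validate_landmarks(reference)
  if (!is.null(groups)) {
    reference <- dplyr::filter(reference, .data$group %in% groups)
    if (nrow(reference) == 0) {
      stop("no reference specimens left after group restriction",
           call. = FALSE)
    }
  }
  ref_ids <- unique(reference$specimen_id)
  if (!is.null(unknowns)) {
    validate_landmarks(unknowns)
    unk <- unknowns
    unk$group <- NA_character_
    keep <- intersect(names(reference),
                      c("specimen_id", "group", "side", "landmark", "x", "y"))
    combined <- dplyr::bind_rows(reference[, keep],
                                 unk[, intersect(names(unk), keep)])
  } else {
    combined <- reference
  }
  fit <- gpa(combined)
  ts <- project_to_tangent(fit)
  is_ref <- ts$meta$specimen_id %in% ref_ids
  pca <- pca_fit(ts$scores[is_ref, , drop = FALSE])
  unk_scores <- NULL
  if (any(!is_ref)) {
    proj <- sweep(ts$scores[!is_ref, , drop = FALSE], 2, pca$mean_row) %*%
      pca$axes
    unk_scores <- tibble::as_tibble(proj, .name_repair = "minimal")
    names(unk_scores) <- colnames(pca$scores)
    unk_scores <- dplyr::bind_cols(
      tibble::tibble(specimen_id = ts$meta$specimen_id[!is_ref]), unk_scores)
  }
  ref_scores <- dplyr::bind_cols(
    ts$meta[is_ref, c("specimen_id", "group")],
    tibble::as_tibble(pca$scores, .name_repair = "minimal") |>
      rlang::set_names(colnames(pca$scores)))
  structure(list(pca = pca, reference_scores = ref_scores,
                 unknown_scores = unk_scores),
            class = "subspace_pca")
}
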