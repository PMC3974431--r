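#' Assemble a pipeline configuration
#'
#' A fully serializable description of one analysis run; an identical config
#' plus identical inputs reproduces identical outputs. Can also be read from
#' a YAML file with [read_pipeline_config()].
#'
#' @param tps path to the reference TPS file.
#' @param metadata path to the sidecar metadata CSV (`specimen_id,group,side`).
#' @param unknowns optional path to a TPS file of unknown configurations.
#' @param output_dir directory for the report bundle.
#' @param priors,n_components,mode analysis knobs (see [lda_fit()] and
#'   [assign_unknowns()]).
#' @param seed integer seed recorded in the manifest.
#' @param verbose logical; log stage progress to stderr.
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(tps, metadata, unknowns = NULL,
                            output_dir = "wingshape_run",
                            priors = "proportional",
                            n_components = "auto",
                            mode = "joint", seed = 1L, verbose = FALSE) {
  structure(list(
    tps = tps, metadata = metadata, unknowns = unknowns,
    output_dir = output_dir, priors = priors,
    n_components = n_components, mode = mode,
    seed = as.integer(seed), verbose = isTRUE(verbose)
  ), class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#' @param path YAML file whose keys mirror the arguments of
#'   [pipeline_config()].
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  vals <- yaml::read_yaml(path)
  do.call(pipeline_config, vals)
}

#' Run the full assignment pipeline
#'
#' Executes superimposition, the tangent adequacy check, PCA, LDA with
#' leave-one-out cross-validation, and (when unknowns are supplied) the
#' a-posteriori assignment. Writes a report bundle into the output
#' directory: aligned coordinates (`aligned.tps`), `adequacy.csv`,
#' `pca_variance.csv`, `confusion.csv` + `hit_ratios.csv`,
#' `assignment.csv` + `assignment_summary.csv`, and a `manifest.yaml`
#' recording every decision knob. Any stage error aborts the run with the
#' stage name, and partial outputs are removed.
#'
#' @param config a `pipeline_config` (or path to a YAML config).
#' @return invisibly, a list with the in-memory results (`gpa`, `adequacy`,
#'   `pca`, `confusion`, `hit_ratios`, `assignment`) and `files`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  log_msg <- function(...) {
    if (config$verbose) message(sprintf(...))
  }
  if (!file.exists(config$tps)) {
    stop("input TPS file not found: ", config$tps, call. = FALSE)
  }
  if (!file.exists(config$metadata)) {
    stop("metadata CSV not found: ", config$metadata, call. = FALSE)
  }
  out_dir <- config$output_dir
  created <- !dir.exists(out_dir)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  stage <- "setup"
  on_fail <- function(e) {
    unlink(files)
    if (created) unlink(out_dir, recursive = TRUE)
    stop(sprintf("pipeline failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  }
  tryCatch({
    stage <- "read"
    log_msg("reading %s", config$tps)
    reference <- read_tps(config$tps, metadata = config$metadata)
    if (anyNA(reference$group)) {
      stop("reference specimens without a group label: ",
           paste(utils::head(unique(
             reference$specimen_id[is.na(reference$group)]), 3),
             collapse = ", "))
    }
    unknowns <- NULL
    if (!is.null(config$unknowns)) {
      unknowns <- read_tps(config$unknowns)
    }

    stage <- "superimpose"
    log_msg("superimposing %d specimens", length(unique(reference$specimen_id)))
    fit <- gpa(reference)
    f_aligned <- file.path(out_dir, "aligned.tps")
    write_tps(dplyr::select(tidy(fit), -dplyr::any_of("scale")), f_aligned)
    files <- c(files, f_aligned)

    stage <- "adequacy"
    adequacy <- tangent_adequacy(fit)
    f_adeq <- file.path(out_dir, "adequacy.csv")
    readr::write_csv(adequacy, f_adeq)
    files <- c(files, f_adeq)

    stage <- "pca"
    ts <- project_to_tangent(fit)
    pca <- pca_fit(ts)
    f_pca <- file.path(out_dir, "pca_variance.csv")
    readr::write_csv(tidy(pca), f_pca)
    files <- c(files, f_pca)

    stage <- "crossvalidate"
    log_msg("leave-one-out cross-validation")
    confusion <- loo_crossvalidate(ts, ts$meta$group,
                                   priors = config$priors,
                                   n_components = config$n_components)
    hr <- hit_ratios(confusion)
    f_conf <- file.path(out_dir, "confusion.csv")
    conf_wide <- tidy(confusion) |>
      tidyr::pivot_wider(names_from = "predicted", values_from = "count")
    readr::write_csv(conf_wide, f_conf)
    f_hr <- file.path(out_dir, "hit_ratios.csv")
    readr::write_csv(
      dplyr::bind_rows(
        hr$per_group,
        tibble::tibble(group = "OVERALL", n = sum(hr$per_group$n),
                       n_correct = sum(hr$per_group$n_correct),
                       hit_ratio = hr$overall_hit_ratio,
                       hit_ratio_display = hr$overall_display)),
      f_hr)
    files <- c(files, f_conf, f_hr)

    assignment <- NULL
    if (!is.null(unknowns)) {
      stage <- "assign"
      log_msg("assigning %d unknown configuration(s)",
              length(unique(unknowns$specimen_id)))
      assignment <- assign_unknowns(reference, unknowns,
                                    priors = config$priors,
                                    n_components = config$n_components,
                                    mode = config$mode)
      f_assign <- file.path(out_dir, "assignment.csv")
      write_assignment_csv(assignment, f_assign)
      files <- c(files, f_assign,
                 file.path(out_dir, "assignment_summary.csv"))
    }

    stage <- "manifest"
    manifest <- list(
      seed = config$seed,
      priors = config$priors,
      n_components_rule = as.character(config$n_components),
      mode = config$mode,
      n_reference = fit$n,
      k = fit$k,
      gpa_iterations = fit$iterations,
      gpa_converged = fit$converged,
      adequacy_slope = adequacy$slope,
      adequacy_correlation = adequacy$correlation,
      retained_components_loo = config$n_components,
      overall_hit_ratio = hr$overall_hit_ratio,
      n_misclassified = hr$n_misclassified
    )
    if (!is.null(assignment)) {
      manifest$assignment_mode <- assignment$options$mode
      manifest$retained_components_assignment <-
        assignment$options$retained_components
    }
    f_manifest <- file.path(out_dir, "manifest.yaml")
    yaml::write_yaml(manifest, f_manifest)
    files <- c(files, f_manifest)

    invisible(list(gpa = fit, adequacy = adequacy, pca = pca,
                   confusion = confusion, hit_ratios = hr,
                   assignment = assignment, files = files,
                   manifest = manifest))
  }, error = on_fail)
}
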