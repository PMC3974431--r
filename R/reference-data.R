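#' Composition of the curated bee-forewing reference collection
#'
#' Per-species specimen counts of the 360-specimen, 15-subfamily reference
#' collection of female bee forewings that the default synthetic design
#' emulates (see [reference_group_sizes()]).
#'
#' @return a tibble with columns `family`, `subfamily`, `species`, `n`.
#' @export
reference_composition <- function() {
  readr::read_csv(
    system.file("extdata", "bee_subfamily_composition.csv",
                package = "wingshape"),
    show_col_types = FALSE,
    col_types = readr::cols(n = "i", .default = "c"))
}

#' Published-scale cross-validation counts for the reference collection
#'
#' The subfamily-level leave-one-out confusion counts reported for the
#' reference collection, as a [confusion_matrix()] object, so hit-ratio
#' bookkeeping can be recomputed from the printed counts.
#'
#' @return a `shape_confusion` object (15 groups, 360 specimens).
#' @export
reference_crossvalidation <- function() {
  tab <- readr::read_csv(
    system.file("extdata", "subfamily_crossvalidation_counts.csv",
                package = "wingshape"),
    show_col_types = FALSE)
  groups <- tab$truth
  counts <- as.matrix(tab[, -1])
  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(truth = groups, predicted = colnames(counts))
  stopifnot(identical(groups, colnames(counts)))
  structure(list(groups = groups, counts = counts),
            class = "shape_confusion")
}
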