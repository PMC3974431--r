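#' Build a landmark tibble from a coordinate matrix
#'
#' The package represents landmark data in long ("tidy") form: one row per
#' landmark per specimen, with columns `specimen_id`, `group`, `side`,
#' `landmark`, `x`, `y` and optionally `scale`. Landmark order encodes the
#' homology correspondence between specimens and is never re-sorted.
#'
#' @param coords numeric matrix with k rows and 2 columns (x, y).
#' @param specimen_id specimen identifier (single string).
#' @param side one of `"left"`, `"right"`, `"unknown"`.
#' @param group optional group label (e.g. subfamily), `NA` if unknown.
#' @param scale optional positive digitizing scale (units per coordinate step).
#' @return a tibble with one row per landmark.
#' @export
#' @examples
#' landmark_data(cbind(c(0, 1, 0), c(0, 0, 1)), "s1")
landmark_data <- function(coords, specimen_id, side = "unknown",
                          group = NA_character_, scale = NA_real_) {
  coords <- as.matrix(coords)
  stopifnot(is.numeric(coords), ncol(coords) == 2)
  if (nrow(coords) < 3) {
    stop("a landmark configuration needs at least 3 landmarks", call. = FALSE)
  }
  if (!all(is.finite(coords))) {
    stop("all landmark coordinates must be finite", call. = FALSE)
  }
  side <- match.arg(side, c("left", "right", "unknown"))
  tibble::tibble(
    specimen_id = as.character(specimen_id),
    group = as.character(group),
    side = side,
    landmark = seq_len(nrow(coords)),
    x = coords[, 1],
    y = coords[, 2],
    scale = as.numeric(scale)
  )
}

#' Validate a landmark tibble
#'
#' Checks the structural invariants the downstream analyses rely on: required
#' columns present, a common landmark count k >= 3 across specimens, finite
#' coordinates, landmarks numbered 1..k within each specimen, and no
#' degenerate (all-coincident) configurations.
#'
#' @param data a landmark tibble (see [landmark_data()]).
#' @return `data`, invisibly, if valid; otherwise an error.
#' @export
validate_landmarks <- function(data) {
  needed <- c("specimen_id", "landmark", "x", "y")
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols) > 0) {
    stop("landmark data lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(data) == 0) stop("landmark data is empty", call. = FALSE)
  if (!all(is.finite(data$x)) || !all(is.finite(data$y))) {
    stop("all landmark coordinates must be finite", call. = FALSE)
  }
  counts <- dplyr::count(data, .data$specimen_id)
  k <- counts$n[1]
  if (any(counts$n != k)) {
    bad <- counts$specimen_id[counts$n != k][1]
    stop(sprintf(
      "landmark counts differ across specimens: '%s' has %d landmarks, expected %d",
      bad, counts$n[counts$n != k][1], k), call. = FALSE)
  }
  if (k < 3) stop("configurations need at least 3 landmarks", call. = FALSE)
  ord_ok <- data |>
    dplyr::group_by(.data$specimen_id) |>
    dplyr::summarise(ok = all(.data$landmark == seq_len(dplyr::n())),
                     .groups = "drop")
  if (!all(ord_ok$ok)) {
    stop("landmarks must be numbered 1..k in order within each specimen",
         call. = FALSE)
  }
  degen <- data |>
    dplyr::group_by(.data$specimen_id) |>
    dplyr::summarise(
      cs = sqrt(sum((.data$x - mean(.data$x))^2 + (.data$y - mean(.data$y))^2)),
      .groups = "drop")
  if (any(degen$cs == 0)) {
    stop(sprintf("degenerate configuration (all landmarks coincide): '%s'",
                 degen$specimen_id[degen$cs == 0][1]), call. = FALSE)
  }
  invisible(data)
}

#' Number of landmarks per configuration
#' @param data a landmark tibble.
#' @return integer k.
#' @export
landmark_count <- function(data) {
  as.integer(dplyr::count(data, .data$specimen_id)$n[1])
}

# Internal: split a landmark tibble into a k x 2 x n array plus per-specimen
# metadata, preserving first-appearance specimen order.
lm_split <- function(data) {
  validate_landmarks(data)
  ids <- unique(data$specimen_id)
  k <- landmark_count(data)
  data <- dplyr::arrange(data, match(.data$specimen_id, ids), .data$landmark)
  arr <- array(NA_real_, dim = c(k, 2, length(ids)),
               dimnames = list(NULL, c("x", "y"), ids))
  arr[, 1, ] <- matrix(data$x, nrow = k)
  arr[, 2, ] <- matrix(data$y, nrow = k)
  meta <- data |>
    dplyr::group_by(.data$specimen_id) |>
    dplyr::slice(1) |>
    dplyr::ungroup() |>
    dplyr::select(dplyr::any_of(c("specimen_id", "group", "side", "scale"))) |>
    dplyr::arrange(match(.data$specimen_id, ids))
  list(coords = arr, meta = meta, k = k, ids = ids)
}

# Internal: rebuild a long landmark tibble from a k x 2 x n array + metadata.
lm_bind <- function(arr, meta) {
  k <- dim(arr)[1]
  n <- dim(arr)[3]
  base <- meta[rep(seq_len(n), each = k), , drop = FALSE]
  base$landmark <- rep(seq_len(k), times = n)
  base$x <- as.vector(arr[, 1, ])
  base$y <- as.vector(arr[, 2, ])
  tibble::as_tibble(base[, c(setdiff(names(meta), c("x", "y", "landmark")),
                             "landmark", "x", "y")])
}

# Internal: vectorize a k x 2 matrix as (x1, y1, x2, y2, ...).
vec_config <- function(m) as.vector(t(m))

# Internal: inverse of vec_config.
unvec_config <- function(v) {
  matrix(v, ncol = 2, byrow = TRUE, dimnames = list(NULL, c("x", "y")))
}

#' Centroid size of each configuration
#'
#' Centroid size is the square root of the summed squared distances of a
#' configuration's landmarks from their centroid -- the standard geometric
#' size measure removed by Procrustes superimposition.
#'
#' @param data a landmark tibble (one or more specimens).
#' @return a tibble with columns `specimen_id` and `centroid_size`.
#' @export
centroid_sizes <- function(data) {
  validate_landmarks(data)
  data |>
    dplyr::group_by(.data$specimen_id) |>
    dplyr::summarise(
      centroid_size = sqrt(sum((.data$x - mean(.data$x))^2 +
                                 (.data$y - mean(.data$y))^2)),
      .groups = "drop")
}

#' Centroid size of a single coordinate matrix
#' @param m a k x 2 numeric matrix.
#' @return positive scalar.
#' @export
centroid_size <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) < 2) stop("need at least 2 landmarks", call. = FALSE)
  cs <- sqrt(sum(sweep(m, 2, colMeans(m))^2))
  if (cs == 0) stop("degenerate configuration: all landmarks coincide",
                    call. = FALSE)
  cs
}

#' Reflect configurations about a vertical axis
#'
#' Negates x-coordinates about each configuration's centroid and flips the
#' `side` flag, turning a left wing into a comparable ("symmetrized") right
#' wing and vice versa. Landmark order is unchanged; if a digitizing protocol
#' requires re-indexing after reflection, supply an integer permutation via
#' `relabel` (position i of `relabel` names the old landmark that becomes
#' landmark i).
#'
#' @param data a landmark tibble.
#' @param relabel optional integer permutation of `1:k` applied after
#'   reflection.
#' @return the reflected landmark tibble.
#' @export
reflect_configuration <- function(data, relabel = NULL) {
  validate_landmarks(data)
  out <- data |>
    dplyr::group_by(.data$specimen_id) |>
    dplyr::mutate(x = 2 * mean(.data$x) - .data$x) |>
    dplyr::ungroup()
  if ("side" %in% names(out)) {
    out$side <- c(left = "right", right = "left",
                  unknown = "unknown")[out$side]
  }
  if (!is.null(relabel)) {
    k <- landmark_count(out)
    if (!setequal(relabel, seq_len(k))) {
      stop("relabel must be a permutation of 1:k", call. = FALSE)
    }
    out <- out |>
      dplyr::group_by(.data$specimen_id) |>
      dplyr::mutate(landmark = match(.data$landmark, relabel)) |>
      dplyr::arrange(.data$landmark, .by_group = TRUE) |>
      dplyr::ungroup()
  }
  out
}
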