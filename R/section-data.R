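#' Bundle a registered section's label mask and cell-feature table
#'
#' A section is represented by a 2D integer label mask (0 = background,
#' each positive integer one nucleus) and a feature table keyed by
#' `cell_id` with pixel-unit centroids (`centroid_x` = 0-based column,
#' `centroid_y` = 0-based row), one numeric column per marker, and an
#' optional `label` column carrying a cell-type annotation. Every positive
#' label in the mask must have exactly one feature row and vice versa.
#'
#' @param mask Integer matrix, non-negative; 0 is background.
#' @param features Data frame with columns `cell_id`, `centroid_x`,
#'   `centroid_y`, marker columns, optional `label`.
#' @param pixel_size Micrometres per pixel (positive). Physical distances
#'   are pixel distances times `pixel_size`.
#' @return An object of class `section_data`.
#' @export
section_data <- function(mask, features, pixel_size = 1) {
  if (!is.matrix(mask) || !is.numeric(mask))
    abort("`mask` must be a numeric matrix.")
  if (any(mask < 0)) abort("`mask` contains negative labels.")
  if (any(mask != floor(mask))) abort("`mask` must be integer-valued.")
  storage.mode(mask) <- "integer"
  if (!is.data.frame(features)) abort("`features` must be a data frame.")
  needed <- c("cell_id", "centroid_x", "centroid_y")
  missing_cols <- setdiff(needed, names(features))
  if (length(missing_cols) > 0L)
    abort(paste0("`features` lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  if (anyDuplicated(features$cell_id))
    abort("`features$cell_id` contains duplicates.")
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || pixel_size <= 0)
    abort("`pixel_size` must be a single positive number.")

  labs <- sort(unique(mask[mask > 0L]))
  ids <- sort(as.integer(features$cell_id))
  if (!identical(labs, ids))
    abort("Mask labels and feature-table cell ids do not agree.")

  structure(
    list(mask = mask, features = tibble::as_tibble(features),
         pixel_size = pixel_size),
    class = "section_data"
  )
}

#' @export
print.section_data <- function(x, ...) {
  cat(sprintf("section_data: %d x %d px mask, %d cells, %d marker(s), %.3g um/px\n",
              nrow(x$mask), ncol(x$mask), nrow(x$features),
              length(marker_columns(x$features)), x$pixel_size))
  invisible(x)
}

# marker columns = everything that is not id/centroid/label
marker_columns <- function(features) {
  setdiff(names(features), c("cell_id", "centroid_x", "centroid_y", "label"))
}

#' Markers measured in both sections
#'
#' @param ref,target `section_data` objects or bare feature tables.
#' @return Character vector of shared marker names, in `ref`'s column
#'   order (the order is fixed and recorded by position).
#' @export
shared_markers <- function(ref, target) {
  intersect(marker_columns(as_feature_table(ref)),
            marker_columns(as_feature_table(target)))
}

#' Z-score marker columns of a feature table
#'
#' Each named marker is centred and scaled using the table's own mean and
#' population (divide-by-n) standard deviation; all other columns are left
#' untouched. The operation is idempotent. It is offered as an explicit
#' pipeline step: the correlation-distance matchers take the feature table
#' as given, and while rank-based costs are usually insensitive to
#' per-marker scaling, the effect is not exactly zero because each marker
#' receives its own affine map.
#'
#' @param features Feature table (data frame).
#' @param markers Character vector of marker columns to standardize;
#'   defaults to all marker columns.
#' @return A new tibble with standardized marker columns.
#' @export
standardize_features <- function(features, markers = NULL) {
  markers <- markers %||% marker_columns(features)
  missing_cols <- setdiff(markers, names(features))
  if (length(missing_cols) > 0L)
    abort(paste0("Marker(s) not in table: ", paste(missing_cols, collapse = ", ")))
  out <- tibble::as_tibble(features)
  n <- nrow(out)
  for (m in markers) {
    v <- out[[m]]
    if (!is.numeric(v)) abort(sprintf("Marker `%s` is not numeric.", m))
    s <- sqrt(sum((v - mean(v))^2) / n)
    if (s == 0) abort(sprintf("Marker `%s` is constant (SD = 0); cannot standardize.", m))
    out[[m]] <- (v - mean(v)) / s
  }
  out
}

#' Spearman correlation distance between two marker vectors
#'
#' The per-pair matching cost `1 - rho` where `rho` is Spearman's rank
#' correlation with average ranks for ties, computed across markers
#' within one candidate cell pair. If either vector is constant the
#' correlation is undefined; the neutral sentinel cost 1.0 is returned
#' with attribute `undefined = TRUE` so that callers can fall back on
#' spatial evidence.
#'
#' @param u,v Numeric vectors of equal length (>= 2), same marker order.
#' @return Cost in \[0, 2\], with attribute `undefined`.
#' @export
spearman_pair_cost <- function(u, v) {
  if (length(u) != length(v)) abort("`u` and `v` have different lengths.")
  if (length(u) < 2L) abort("Need at least 2 markers for a correlation cost.")
  ru <- rank(u)
  rv <- rank(v)
  if (sd(ru) == 0 || sd(rv) == 0)
    return(structure(1.0, undefined = TRUE))
  structure(1 - cor(ru, rv), undefined = FALSE)
}

#' Per-marker correlation of matched cells (match quality)
#'
#' For each shared marker, the Spearman correlation between the reference
#' and target intensities across matched pairs; the unweighted mean over
#' markers is the match quality. This is computed *across pairs within
#' one marker* and is distinct from [spearman_pair_cost()], which is
#' computed across markers within one pair.
#'
#' @param matches A match table (`ref_id`, `target_id`), e.g. from
#'   [track_cells()] or [coexist_match()]; at least 3 pairs.
#' @param ref,target `section_data` objects or bare feature tables.
#' @param markers Shared marker names; defaults to [shared_markers()].
#' @return Object of class `match_correlation`: list with `per_marker`
#'   (tibble of `marker`, `rho`; `NA` where a marker is constant across
#'   pairs), `mean_rho` (mean over defined markers), `n_undefined`.
#' @export
match_correlation <- function(matches, ref, target, markers = NULL) {
  markers <- markers %||% shared_markers(ref, target)
  if (length(markers) == 0L) abort("No shared markers.")
  if (nrow(matches) < 3L) abort("Need at least 3 matched pairs.")
  rf <- as_feature_table(ref)
  tf <- as_feature_table(target)
  fr <- rf[match(matches$ref_id, rf$cell_id), , drop = FALSE]
  ft <- tf[match(matches$target_id, tf$cell_id), , drop = FALSE]
  if (anyNA(fr$cell_id) || anyNA(ft$cell_id))
    abort("Match table contains cell ids absent from the section tables.")
  rho <- vapply(markers, function(m) {
    a <- fr[[m]]; b <- ft[[m]]
    if (sd(a) == 0 || sd(b) == 0) return(NA_real_)
    cor(a, b, method = "spearman")
  }, numeric(1))
  n_undef <- sum(is.na(rho))
  if (n_undef > 0L)
    warn(sprintf("%d marker(s) constant across pairs; excluded from the mean.",
                 n_undef))
  structure(
    list(per_marker = tibble::tibble(marker = markers, rho = unname(rho)),
         mean_rho = mean(rho, na.rm = TRUE),
         n_undefined = n_undef),
    class = "match_correlation"
  )
}

#' @export
print.match_correlation <- function(x, ...) {
  cat(sprintf("match quality (mean Spearman over %d markers): %.4f\n",
              nrow(x$per_marker), x$mean_rho))
  invisible(x)
}

#' @export
tidy.match_correlation <- function(x, ...) x$per_marker

#' @export
glance.match_correlation <- function(x, ...) {
  tibble::tibble(mean_rho = x$mean_rho,
                 n_markers = nrow(x$per_marker),
                 n_undefined = x$n_undefined)
}

#' Construct a validated bijective match set
#'
#' @param ref_id,target_id Paired cell ids; each side must be free of
#'   duplicates (bijectivity).
#' @param cost Per-pair cost (0 for purely spatial tracking).
#' @param overlap_pixels Per-pair pixel overlap (non-negative).
#' @return A tibble of class `match_set` with columns `ref_id`,
#'   `target_id`, `cost`, `overlap_pixels`.
#' @export
match_set <- function(ref_id = integer(), target_id = integer(),
                      cost = numeric(length(ref_id)),
                      overlap_pixels = integer(length(ref_id))) {
  if (anyDuplicated(ref_id) || anyDuplicated(target_id))
    abort("A match set must be bijective: duplicated ref or target ids.")
  if (any(overlap_pixels < 0)) abort("`overlap_pixels` must be non-negative.")
  out <- tibble::tibble(ref_id = as.integer(ref_id),
                        target_id = as.integer(target_id),
                        cost = as.numeric(cost),
                        overlap_pixels = as.integer(overlap_pixels))
  class(out) <- c("match_set", class(out))
  out
}
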