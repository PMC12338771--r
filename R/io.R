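#' Read an integer label mask from a single-plane TIFF
#'
#' @param path Path to an unsigned-integer, single-channel TIFF.
#' @return Integer matrix (0 = background).
#' @export
read_label_mask <- function(path) {
  if (!file.exists(path)) abort(sprintf("Mask file not found: %s", path))
  img <- tiff::readTIFF(path, as.is = TRUE)
  if (length(dim(img)) != 2L)
    abort(sprintf("%s is not a single-channel image (dims: %s).",
                  path, paste(dim(img), collapse = "x")))
  # float sample data reinterpreted by as.is shows up as garbage negatives
  if (!is.integer(img) || any(img < 0))
    abort(sprintf("%s is not an unsigned-integer TIFF.", path))
  img
}

#' Write an integer label mask as a 16-bit TIFF
#'
#' @param mask Integer matrix with labels below 65536.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_label_mask <- function(mask, path) {
  if (!is.matrix(mask) || any(mask < 0) || any(mask != floor(mask)))
    abort("`mask` must be a non-negative integer matrix.")
  if (max(mask) > 65535)
    abort("Labels above 65535 cannot be stored in a 16-bit mask.")
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tif")
  tiff::writeTIFF(mask / 65535, tmp, bits.per.sample = 16L)
  file.rename(tmp, path)
  invisible(path)
}

cli_header <- function(params = NULL) {
  v <- as.character(utils::packageVersion("coexist"))
  extra <- if (length(params) > 0L)
    paste0(" | ", paste(names(params), unlist(params), sep = "=",
                        collapse = " ")) else ""
  paste0("# coexist ", v, extra)
}

write_table_with_header <- function(df, path, params = NULL) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".csv")
  body <- readr::format_csv(df)
  writeLines(c(cli_header(params), sub("\n$", "", body)), tmp)
  file.rename(tmp, path)
  invisible(path)
}

#' Read a cell-feature table
#'
#' Expects a comma-separated file with header columns `cell_id`,
#' `centroid_x`, `centroid_y`, one numeric column per marker and an
#' optional `label` column. Lines starting with `#` are comments.
#'
#' @param path Path to the CSV file.
#' @return Tibble with typed columns; duplicate cell ids are rejected.
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) abort(sprintf("Feature table not found: %s", path))
  df <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                        progress = FALSE)
  needed <- c("cell_id", "centroid_x", "centroid_y")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols) > 0L)
    abort(sprintf("%s lacks column(s): %s", path,
                  paste(missing_cols, collapse = ", ")))
  if (anyDuplicated(df$cell_id))
    abort(sprintf("%s contains duplicated cell_id values.", path))
  for (m in marker_columns(df))
    if (!is.numeric(df[[m]]))
      abort(sprintf("Marker column `%s` in %s is not numeric.", m, path))
  df
}

#' Write a cell-feature table
#'
#' @param features Feature table.
#' @param path Output path (CSV; a `#` header records version and
#'   parameters).
#' @param params Optional named list echoed into the header comment.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(features, path, params = NULL) {
  write_table_with_header(features, path, params)
}

#' Read a match table
#'
#' @param path CSV with columns `ref_id`, `target_id`, `cost`,
#'   `overlap_pixels`.
#' @return A [match_set()].
#' @export
read_matches <- function(path) {
  if (!file.exists(path)) abort(sprintf("Match file not found: %s", path))
  df <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                        progress = FALSE)
  needed <- c("ref_id", "target_id")
  if (!all(needed %in% names(df)))
    abort(sprintf("%s lacks ref_id/target_id columns.", path))
  match_set(ref_id = df$ref_id, target_id = df$target_id,
            cost = df$cost %||% rep(0, nrow(df)),
            overlap_pixels = df$overlap_pixels %||% rep(0L, nrow(df)))
}

#' Write a match table
#'
#' @param ms A [match_set()].
#' @param path Output path.
#' @param params Optional named list echoed into the header comment.
#' @return `path`, invisibly.
#' @export
write_matches <- function(ms, path, params = NULL) {
  write_table_with_header(ms, path, params)
}

# accept a section_data or a bare feature table
as_feature_table <- function(x) {
  if (inherits(x, "section_data")) x$features else tibble::as_tibble(x)
}
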