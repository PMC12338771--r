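#' Extract nucleus regions from a label mask
#'
#' @param mask Integer label matrix (0 = background).
#' @return Tibble with one row per positive label: `label`, `n_pixels`,
#'   `centroid_row`, `centroid_col` (0-based pixel indices; the centroid
#'   is the unweighted mean of the region's pixel coordinates) and a
#'   list-column `pixels` of 2-column (row, col) matrices.
#' @export
extract_regions <- function(mask) {
  if (!is.matrix(mask) || !is.numeric(mask))
    abort("`mask` must be a numeric matrix.")
  if (any(mask < 0)) abort("`mask` contains negative labels.")
  idx <- which(mask > 0)
  if (length(idx) == 0L)
    return(tibble::tibble(label = integer(), n_pixels = integer(),
                          centroid_row = numeric(), centroid_col = numeric(),
                          pixels = list()))
  rc <- arrayInd(idx, dim(mask)) - 1L     # 0-based (row, col)
  lab <- as.integer(mask[idx])
  ord <- order(lab)
  lab <- lab[ord]; rc <- rc[ord, , drop = FALSE]
  split_idx <- split(seq_along(lab), lab)
  tibble::tibble(
    label = as.integer(names(split_idx)),
    n_pixels = unname(lengths(split_idx)),
    centroid_row = unname(vapply(split_idx, function(i) mean(rc[i, 1]),
                                 numeric(1))),
    centroid_col = unname(vapply(split_idx, function(i) mean(rc[i, 2]),
                                 numeric(1))),
    pixels = unname(lapply(split_idx, function(i) rc[i, , drop = FALSE]))
  )
}

# pixel-overlap counts between every pair of labels sharing a pixel
mask_overlap_pairs <- function(ref_mask, tgt_mask) {
  both <- ref_mask > 0L & tgt_mask > 0L
  if (!any(both))
    return(tibble::tibble(ref_label = integer(), target_label = integer(),
                          overlap = integer()))
  a <- as.integer(ref_mask[both])
  b <- as.integer(tgt_mask[both])
  key <- paste(a, b)
  tab <- table(key)
  parts <- strsplit(names(tab), " ", fixed = TRUE)
  tibble::tibble(
    ref_label = vapply(parts, function(p) as.integer(p[1]), integer(1)),
    target_label = vapply(parts, function(p) as.integer(p[2]), integer(1)),
    overlap = as.integer(tab)
  )
}

# 0-based centroids of every positive label, as a lookup matrix
mask_centroids <- function(mask) {
  idx <- which(mask > 0)
  lab <- as.integer(mask[idx])
  rc <- arrayInd(idx, dim(mask)) - 1L
  rows <- tapply(rc[, 1], lab, mean)
  cols <- tapply(rc[, 2], lab, mean)
  cbind(row = rows, col = cols)   # dimnames[[1]] are labels
}

# annotate overlap pairs with inter-centroid pixel distance
add_pair_distances <- function(pairs, ref_cent, tgt_cent) {
  rc <- ref_cent[as.character(pairs$ref_label), , drop = FALSE]
  tc <- tgt_cent[as.character(pairs$target_label), , drop = FALSE]
  pairs$dist <- sqrt((rc[, 1] - tc[, 1])^2 + (rc[, 2] - tc[, 2])^2)
  pairs
}

# best candidate per group under an ordering; key_cols in tie-chain order
best_per_group <- function(pairs, group_col, key_cols) {
  ord <- do.call(order, c(unname(pairs[c(group_col, key_cols)]), list(method = "radix")))
  pairs <- pairs[ord, , drop = FALSE]
  pairs[!duplicated(pairs[[group_col]]), , drop = FALSE]
}

#' Track cells across sections by overlap majority vote
#'
#' The purely spatial baseline matcher. Forward pass: for each reference
#' nucleus, the candidates are the target labels present at its pixel
#' coordinates, and the candidate with maximum pixel overlap wins (ties
#' broken by minimum centroid distance, then lowest label id). Reverse
#' pass: the same rule applied from the assigned target nucleus over its
#' full footprint; the pair is kept only if it maps back to the original
#' reference nucleus. The result is bijective and cycle-consistent by
#' construction: swapping the sections yields the identical pair set.
#'
#' @param ref,target `section_data` objects on the same pixel grid.
#' @return A [match_set()] tibble; `cost` is 0 (tracking uses no
#'   molecular information) and `overlap_pixels` records the shared
#'   footprint.
#' @export
track_cells <- function(ref, target) {
  check_same_grid(ref, target)
  pairs <- mask_overlap_pairs(ref$mask, target$mask)
  if (nrow(pairs) == 0L) return(match_set())
  pairs <- add_pair_distances(pairs,
                              mask_centroids(ref$mask),
                              mask_centroids(target$mask))
  pairs$neg_overlap <- -pairs$overlap

  fwd <- best_per_group(pairs, "ref_label",
                        c("neg_overlap", "dist", "target_label"))
  rev <- best_per_group(pairs, "target_label",
                        c("neg_overlap", "dist", "ref_label"))
  rev_best <- rev$ref_label[match(fwd$target_label, rev$target_label)]
  keep <- fwd[rev_best == fwd$ref_label, , drop = FALSE]
  match_set(ref_id = keep$ref_label, target_id = keep$target_label,
            cost = 0, overlap_pixels = keep$overlap)
}

check_same_grid <- function(ref, target) {
  if (!inherits(ref, "section_data") || !inherits(target, "section_data"))
    abort("`ref` and `target` must be section_data objects.")
  if (!identical(dim(ref$mask), dim(target$mask)))
    abort("Masks have different shapes; register the sections onto a common grid first.")
}
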