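#' Build a spatially constrained Spearman-distance cost matrix
#'
#' Pairwise cost `1 - Spearman's rho` over the shared markers, computed
#' for *feasible* pairs only: those whose centroid distance (in
#' micrometres, via `pixel_size`) is at most `radius_um`. Infeasible
#' pairs are marked structurally and can never enter a solution; they are
#' never represented by a large finite cost. With `radius_um = Inf` all
#' pairs are computed (the unconstrained, bulk-level baseline).
#'
#' @param ref,target `section_data` objects.
#' @param markers Shared marker names (defaults to [shared_markers()]).
#' @param radius_um Feasibility radius in micrometres, or `Inf` for
#'   unbounded matching. There is no default radius: it is an empirical,
#'   dataset-level choice.
#' @param ref_ids Optional subset of reference cell ids (anchor rows);
#'   defaults to all reference cells.
#' @return Object of class `cost_matrix` with fields `cost`, `feasible`,
#'   `undefined` (pairs where either rank vector is constant; sentinel
#'   cost 1.0), `dist_um`, `ref_ids`, `target_ids`, `radius_um`.
#' @export
build_cost_matrix <- function(ref, target, markers = NULL, radius_um = Inf,
                              ref_ids = NULL) {
  markers <- markers %||% shared_markers(ref, target)
  if (length(markers) == 0L) abort("No shared markers between the sections.")
  if (ref$pixel_size != target$pixel_size)
    abort("Sections have different pixel sizes.")
  fr <- ref$features
  if (!is.null(ref_ids)) {
    keep <- match(ref_ids, fr$cell_id)
    if (anyNA(keep)) abort("`ref_ids` contains ids absent from `ref`.")
    fr <- fr[keep, , drop = FALSE]
  }
  ft <- target$features

  dx <- outer(fr$centroid_x, ft$centroid_x, "-")
  dy <- outer(fr$centroid_y, ft$centroid_y, "-")
  dist_um <- sqrt(dx^2 + dy^2) * ref$pixel_size

  zr <- rank_normalize_rows(as.matrix(fr[, markers, drop = FALSE]))
  zt <- rank_normalize_rows(as.matrix(ft[, markers, drop = FALSE]))
  rho <- zr$z %*% t(zt$z)
  cost <- 1 - rho
  undefined <- outer(!zr$defined, !zt$defined, "|")
  cost[undefined] <- 1.0

  structure(
    list(cost = cost, feasible = dist_um <= radius_um,
         undefined = undefined, dist_um = dist_um,
         ref_ids = as.integer(fr$cell_id),
         target_ids = as.integer(ft$cell_id),
         radius_um = radius_um),
    class = "cost_matrix"
  )
}

# row-wise average ranks, centred and L2-normalized; constant rows flagged
rank_normalize_rows <- function(x) {
  if (ncol(x) == 1L) {
    r <- matrix(1, nrow(x), 1L)
  } else {
    r <- t(apply(x, 1L, rank))
  }
  rc <- r - rowMeans(r)
  nrm <- sqrt(rowSums(rc^2))
  defined <- nrm > 0
  z <- rc / pmax(nrm, 1)
  z[!defined, ] <- 0
  list(z = z, defined = defined)
}

# restrict an existing cost matrix to a new feasibility radius
set_radius <- function(cm, radius_um) {
  cm$feasible <- cm$dist_um <= radius_um
  cm$radius_um <- radius_um
  cm
}

#' Minimum-cost one-to-one assignment over feasible pairs
#'
#' Rectangular linear sum assignment by shortest augmenting paths with
#' dual potentials (Jonker-Volgenant style), restricted to the feasible
#' pairs of a [build_cost_matrix()] result. Unequal set sizes are
#' allowed; a reference cell for which no augmenting path over feasible
#' pairs exists is reported unmatched rather than raising an error. The
#' returned solution is asserted to use no infeasible entry.
#'
#' @param cm A `cost_matrix`.
#' @return A [match_set()] with per-pair costs (`overlap_pixels` is 0:
#'   assignment uses no mask information). Unmatched reference ids are
#'   attached as attribute `unmatched_ref`.
#' @export
constrained_lsa <- function(cm) {
  if (!inherits(cm, "cost_matrix")) abort("`cm` must be a cost_matrix.")
  cc <- cm$cost
  cc[!cm$feasible] <- Inf
  if (!any(is.finite(cc))) abort("No feasible pair under the current radius.")
  col_of <- lsa_augmenting_paths(cc)
  matched <- which(!is.na(col_of))
  costs <- cc[cbind(matched, col_of[matched])]
  if (any(!is.finite(costs)))
    abort("Internal error: assignment used an infeasible entry.")
  out <- match_set(ref_id = cm$ref_ids[matched],
                   target_id = cm$target_ids[col_of[matched]],
                   cost = costs,
                   overlap_pixels = integer(length(matched)))
  attr(out, "unmatched_ref") <- cm$ref_ids[is.na(col_of)]
  out
}

# Min-cost maximum-cardinality rectangular assignment by successive
# shortest augmenting paths with dual potentials (Jonker-Volgenant
# style). `cc` may contain Inf (structurally infeasible); each
# augmentation runs Dijkstra from a virtual source joined to every
# unassigned row, so rows that cannot be matched are simply left
# unmatched while the matched set attains minimum total cost.
# Returns the matched column per row (NA where unmatched).
lsa_augmenting_paths <- function(cc) {
  n <- nrow(cc); m <- ncol(cc)
  u <- numeric(n); v <- numeric(m)
  col_of <- rep(NA_integer_, n)
  row_of <- rep(NA_integer_, m)
  repeat {
    sources <- which(is.na(col_of))
    if (length(sources) == 0L) break
    shortest <- rep(Inf, m)
    path_row <- rep(NA_integer_, m)
    done <- rep(FALSE, m)
    for (i in sources) {
      rc <- cc[i, ] - u[i] - v
      upd <- rc < shortest
      if (any(upd)) { shortest[upd] <- rc[upd]; path_row[upd] <- i }
    }
    sink <- NA_integer_
    minval <- 0
    repeat {
      free <- which(!done)
      if (length(free) == 0L) break
      j <- free[which.min(shortest[free])]
      if (!is.finite(shortest[j])) break
      minval <- shortest[j]
      done[j] <- TRUE
      if (is.na(row_of[j])) { sink <- j; break }
      i <- row_of[j]
      rc <- minval + cc[i, ] - u[i] - v
      upd <- !done & rc < shortest
      if (any(upd)) { shortest[upd] <- rc[upd]; path_row[upd] <- i }
    }
    if (is.na(sink)) break   # no augmenting path: remaining rows unmatched
    sc <- which(done)
    tree_rows <- row_of[sc]
    tree_rows <- tree_rows[!is.na(tree_rows)]
    for (i in tree_rows) u[i] <- u[i] + minval - shortest[col_of[i]]
    u[sources] <- u[sources] + minval
    v[sc] <- v[sc] - (minval - shortest[sc])
    j <- sink
    repeat {
      i <- path_row[j]
      row_of[j] <- i
      tmp <- col_of[i]
      col_of[i] <- j
      if (is.na(tmp)) break
      j <- tmp
    }
  }
  col_of
}

#' Match cells across sections by overlap candidates and shared-marker cost
#'
#' The combined matcher: candidate pairs are gathered exactly as in
#' [track_cells()] (target labels under each reference nucleus's
#' footprint), but within the candidates the assignment minimizes the
#' Spearman correlation distance of the shared markers rather than the
#' pixel overlap. A reverse pass from the chosen target nucleus over its
#' full footprint must map back to the original reference nucleus for
#' the pair to be kept, so the result is bijective and swapping the
#' sections yields the identical pair set. Costs are computed only for
#' overlap candidates, so total work is linear in the number of cells
#' for bounded candidate counts.
#'
#' Cost ties are broken by larger overlap, then smaller centroid
#' distance, then lowest label id. Pairs whose rank vectors are constant
#' (undefined correlation) carry the sentinel cost 1.0 but lose to any
#' defined cost; among themselves they fall back to the overlap rule.
#' With no shared markers the matcher degrades to [track_cells()].
#'
#' @param ref,target `section_data` objects on the same pixel grid.
#' @param markers Shared marker names (default [shared_markers()]); if
#'   empty, tracking is used.
#' @return A [match_set()] with per-pair cost and pixel overlap.
#' @export
coexist_match <- function(ref, target, markers = NULL) {
  check_same_grid(ref, target)
  markers <- markers %||% shared_markers(ref, target)
  if (length(markers) == 0L) return(track_cells(ref, target))

  pairs <- mask_overlap_pairs(ref$mask, target$mask)
  if (nrow(pairs) == 0L) return(match_set())
  pairs <- add_pair_distances(pairs,
                              mask_centroids(ref$mask),
                              mask_centroids(target$mask))
  pairs$neg_overlap <- -pairs$overlap

  # lazy costs: rank-normalize only the cells that appear in a candidate pair
  fr <- ref$features; ft <- target$features
  ridx <- match(pairs$ref_label, fr$cell_id)
  tidx <- match(pairs$target_label, ft$cell_id)
  zr <- rank_normalize_rows(as.matrix(fr[, markers, drop = FALSE]))
  zt <- rank_normalize_rows(as.matrix(ft[, markers, drop = FALSE]))
  rho <- rowSums(zr$z[ridx, , drop = FALSE] * zt$z[tidx, , drop = FALSE])
  pairs$undefined <- !zr$defined[ridx] | !zt$defined[tidx]
  pairs$cost <- ifelse(pairs$undefined, 1.0, 1 - rho)

  key <- c("undefined", "cost", "neg_overlap", "dist")
  fwd <- best_per_group(pairs, "ref_label", c(key, "target_label"))
  rev <- best_per_group(pairs, "target_label", c(key, "ref_label"))
  rev_best <- rev$ref_label[match(fwd$target_label, rev$target_label)]
  keep <- fwd[rev_best == fwd$ref_label, , drop = FALSE]
  match_set(ref_id = keep$ref_label, target_id = keep$target_label,
            cost = keep$cost, overlap_pixels = keep$overlap)
}

# candidate sets per reference label (instrumentation hook used by tests:
# COEXIST considers exactly the tracking candidates, only the selection
# rule differs)
overlap_candidates <- function(ref, target) {
  pairs <- mask_overlap_pairs(ref$mask, target$mask)
  split(pairs$target_label, pairs$ref_label)
}
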