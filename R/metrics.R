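#' Cycle consistency between forward and reverse match sets
#'
#' Fraction of anchors on which matching ref -> target and matching
#' target -> ref agree: the size of the intersection between the forward
#' pairs and the role-swapped reverse pairs, relative to `n_anchors`.
#'
#' @param forward Match set from reference to target.
#' @param reverse Match set from target to reference.
#' @param n_anchors Number of anchors `N` (positive).
#' @return Fraction in \[0, 1\].
#' @export
cycle_consistency_fraction <- function(forward, reverse, n_anchors) {
  if (n_anchors <= 0) abort("`n_anchors` must be positive.")
  f <- paste(forward$ref_id, forward$target_id)
  r <- paste(reverse$target_id, reverse$ref_id)
  length(intersect(f, r)) / n_anchors
}

#' Fraction of original pairs recovered after perturbation
#'
#' @param original,perturbed Match sets; `original` must be non-empty.
#' @return Fraction of `original` pairs present identically in
#'   `perturbed`.
#' @export
pair_recovery <- function(original, perturbed) {
  if (nrow(original) == 0L) abort("`original` match set is empty.")
  o <- paste(original$ref_id, original$target_id)
  p <- paste(perturbed$ref_id, perturbed$target_id)
  mean(o %in% p)
}

#' Precision, recall and F1 of a pairing against ground truth
#'
#' @param ms Match set (`ref_id`, `target_id`).
#' @param truth Ground-truth pair table (`ref_id`, `target_id`), e.g.
#'   from [ground_truth_pairs()].
#' @return One-row tibble `precision`, `recall`, `f1`, `n_matched`,
#'   `n_truth`.
#' @export
pairing_scores <- function(ms, truth) {
  if (nrow(truth) == 0L) abort("`truth` is empty.")
  m <- paste(ms$ref_id, ms$target_id)
  t_ <- paste(truth$ref_id, truth$target_id)
  tp <- length(intersect(m, t_))
  precision <- if (length(m) > 0L) tp / length(m) else 0
  recall <- tp / length(t_)
  f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  tibble::tibble(precision = precision, recall = recall, f1 = f1,
                 n_matched = nrow(ms), n_truth = nrow(truth))
}

#' Anchored LSA radius sweep
#'
#' Reproduces the anchor benchmark: identify `N` anchors (tracked,
#' random, or none = all reference cells), then run the spatially
#' constrained assignment at each radius, scoring the mean shared-marker
#' correlation of the resulting pairs. Random anchors are redrawn for
#' each of `n_seeds` seeds (default 5).
#'
#' @param ref,target `section_data` objects.
#' @param markers Shared markers (default [shared_markers()]).
#' @param radii Radii in micrometres.
#' @param anchor_mode One of `"tracked"`, `"random"`, `"none"`.
#' @param n_seeds Number of random-anchor draws (random mode only).
#' @param seed Base seed for random anchors.
#' @return Tibble of class `radius_sweep`: `radius_um`, `anchor_mode`,
#'   `seed` (`NA` unless random), `quality` (mean shared-marker
#'   correlation; `NA` when fewer than 3 pairs), `n_pairs`.
#' @export
anchored_radius_sweep <- function(ref, target, markers = NULL, radii,
                                  anchor_mode = c("tracked", "random", "none"),
                                  n_seeds = 5, seed = 1) {
  anchor_mode <- match.arg(anchor_mode)
  markers <- markers %||% shared_markers(ref, target)
  tracked <- track_cells(ref, target)
  n_anchors <- nrow(tracked)
  if (anchor_mode != "none" && n_anchors < 3L)
    abort("Tracking produced fewer than 3 anchors.")

  sweep_one <- function(anchor_ids, seed_val) {
    cm <- build_cost_matrix(ref, target, markers, radius_um = max(radii),
                            ref_ids = anchor_ids)
    purrr::map_dfr(radii, function(r) {
      cmr <- set_radius(cm, r)
      q <- NA_real_
      n_pairs <- 0L
      if (any(cmr$feasible)) {
        ms <- constrained_lsa(cmr)
        n_pairs <- nrow(ms)
        if (n_pairs >= 3L)
          q <- suppressWarnings(match_correlation(ms, ref, target, markers)$mean_rho)
      }
      tibble::tibble(radius_um = r, anchor_mode = anchor_mode,
                     seed = seed_val, quality = q, n_pairs = n_pairs)
    })
  }

  out <- switch(
    anchor_mode,
    tracked = sweep_one(tracked$ref_id, NA_integer_),
    none = sweep_one(NULL, NA_integer_),
    random = purrr::map_dfr(seq_len(n_seeds), function(s) {
      set.seed(seed + s - 1L)
      ids <- sample(ref$features$cell_id, n_anchors)
      sweep_one(ids, s)
    })
  )
  class(out) <- c("radius_sweep", class(out))
  out
}

#' @export
autoplot.radius_sweep <- function(object, ...) {
  df <- dplyr::summarise(
    dplyr::group_by(object, .data$radius_um, .data$anchor_mode),
    quality = mean(.data$quality, na.rm = TRUE), .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$radius_um, y = .data$quality,
                                   colour = .data$anchor_mode)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "radius (um)", y = "mean shared-marker correlation",
                  colour = "anchors")
}

#' Cycle consistency of constrained LSA across radii
#'
#' Matches the tracked reference anchors against all target cells, then
#' the tracked target anchors against all reference cells, and reports
#' the fraction of agreeing pairs relative to the anchor count `N` at
#' each radius. Radii are shared between the two directions.
#'
#' @inheritParams anchored_radius_sweep
#' @return Tibble `radius_um`, `cycle_consistency`, `n_anchors`.
#' @export
lsa_cycle_consistency_sweep <- function(ref, target, markers = NULL, radii) {
  markers <- markers %||% shared_markers(ref, target)
  tracked <- track_cells(ref, target)
  if (nrow(tracked) < 1L) abort("Tracking produced no anchors.")
  cm_f <- build_cost_matrix(ref, target, markers, radius_um = max(radii),
                            ref_ids = tracked$ref_id)
  cm_r <- build_cost_matrix(target, ref, markers, radius_um = max(radii),
                            ref_ids = tracked$target_id)
  purrr::map_dfr(radii, function(r) {
    fw <- constrained_lsa(set_radius(cm_f, r))
    rv <- constrained_lsa(set_radius(cm_r, r))
    tibble::tibble(
      radius_um = r,
      cycle_consistency = cycle_consistency_fraction(fw, rv, nrow(tracked)),
      n_anchors = nrow(tracked))
  })
}

#' Match recovery under rigid misregistration
#'
#' Applies each rotation/translation to the target section, re-runs the
#' combined matcher, and reports the fraction of the unperturbed match
#' pairs that are recovered.
#'
#' @param ref,target `section_data` objects.
#' @param markers Shared markers (default [shared_markers()]).
#' @param rotations Rotations in radians.
#' @param translations List of length-2 pixel translations (recycled
#'   against `rotations` as a full grid).
#' @return Tibble of class `recovery_sweep`: `rotation`,
#'   `translation_x`, `translation_y`, `recovery`.
#' @export
misregistration_recovery <- function(ref, target, markers = NULL,
                                     rotations = 0,
                                     translations = list(c(0, 0))) {
  markers <- markers %||% shared_markers(ref, target)
  baseline <- coexist_match(ref, target, markers)
  grid <- tidyr::expand_grid(rotation = rotations,
                             translation = translations)
  out <- purrr::pmap_dfr(grid, function(rotation, translation) {
    pert <- apply_misregistration(target, rotation, translation)
    ms <- coexist_match(ref, pert, markers)
    tibble::tibble(rotation = rotation,
                   translation_x = translation[1],
                   translation_y = translation[2],
                   recovery = pair_recovery(baseline, ms))
  })
  class(out) <- c("recovery_sweep", class(out))
  out
}

#' @export
autoplot.recovery_sweep <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$rotation, y = .data$recovery)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "rotation (rad)", y = "pair recovery")
}
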