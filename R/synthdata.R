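#' Configuration for the synthetic serial-section generator
#'
#' The generator emulates the statistical structure the matching method
#' assumes: spherical nuclei with zero-truncated normally distributed
#' diameters, centers uniformly distributed in a tissue slab (hard-sphere
#' minimum separation), sectioning into consecutive slices of thickness
#' `section_thickness`, two marker panels with a shared subset measured on
#' alternating sections, and independent per-section measurement noise.
#' The z-extent of the slab is derived automatically as
#' `[-(M + 6 S) / 2, n_sections * W + (M + 6 S) / 2]` so that every
#' nucleus that could touch a section is sampled uniformly.
#'
#' @param slab_size Lateral slab extent `c(x, y)` in micrometres.
#' @param section_thickness Section thickness `W` in micrometres.
#' @param n_sections Number of consecutive sections (default 2).
#' @param nucleus_density Nuclei per 100 x 100 um^2 of slab cross-section
#'   (through the full z-extent); ignored when `n_nuclei` is given.
#' @param n_nuclei Optional explicit nucleus count.
#' @param diameter_mean,diameter_sd Nuclear diameter distribution in
#'   micrometres (defaults 7.8 and 2.4, typical of breast-cancer TMA
#'   nuclei).
#' @param min_center_separation Hard-sphere minimum center separation in
#'   micrometres.
#' @param n_cell_types Number of cell types.
#' @param n_markers_panel_a,n_markers_panel_b Panel sizes including the
#'   shared subset.
#' @param n_shared_markers Markers present in both panels (default 8).
#' @param type_separation SD of the per-type archetype log-intensities;
#'   larger values separate the types more.
#' @param cell_level_sd SD of per-cell (log-normal) variation around the
#'   type archetype; this individuality is what makes the shared markers
#'   informative for matching the *same* cell.
#' @param signal_to_noise Ratio of the archetype spread
#'   (`type_separation`) to the per-section measurement noise SD
#'   (default 2, i.e. noise SD is half the archetype spread).
#' @param pixel_size Micrometres per pixel for rasterization.
#' @param seed Integer seed.
#' @return A list of class `synthetic_tissue_config`.
#' @export
synthetic_tissue_config <- function(slab_size = c(300, 300),
                                    section_thickness = 5,
                                    n_sections = 2,
                                    nucleus_density = 90,
                                    n_nuclei = NULL,
                                    diameter_mean = 7.8,
                                    diameter_sd = 2.4,
                                    min_center_separation = 4,
                                    n_cell_types = 5,
                                    n_markers_panel_a = 16,
                                    n_markers_panel_b = 16,
                                    n_shared_markers = 8,
                                    type_separation = 2,
                                    cell_level_sd = 1,
                                    signal_to_noise = 2,
                                    pixel_size = 0.65,
                                    seed = 1) {
  if (section_thickness <= 0) abort("`section_thickness` must be positive.")
  if (min_center_separation < 0) abort("`min_center_separation` must be >= 0.")
  if (n_shared_markers > min(n_markers_panel_a, n_markers_panel_b))
    abort("`n_shared_markers` exceeds a panel size.")
  if (is.null(n_nuclei))
    n_nuclei <- round(nucleus_density * prod(slab_size) / 1e4)
  if (n_nuclei < 1) abort("Configuration yields no nuclei.")
  structure(
    list(slab_size = slab_size, section_thickness = section_thickness,
         n_sections = n_sections, n_nuclei = as.integer(n_nuclei),
         diameter_mean = diameter_mean, diameter_sd = diameter_sd,
         min_center_separation = min_center_separation,
         n_cell_types = n_cell_types,
         n_markers_panel_a = n_markers_panel_a,
         n_markers_panel_b = n_markers_panel_b,
         n_shared_markers = n_shared_markers,
         type_separation = type_separation,
         cell_level_sd = cell_level_sd,
         signal_to_noise = signal_to_noise,
         pixel_size = pixel_size, seed = seed),
    class = "synthetic_tissue_config"
  )
}

#' Generate 3D nuclei with types and latent expression
#'
#' Places `n_nuclei` sphere centers uniformly in the slab with rejection
#' sampling below the hard-sphere separation, draws zero-truncated normal
#' diameters, assigns each nucleus a cell type, and builds its latent
#' log-expression vector as type archetype plus per-cell normal variation
#' (log-normal on the intensity scale).
#'
#' @param config A [synthetic_tissue_config()].
#' @return Object of class `synthetic_tissue`: list with `nuclei`
#'   (tibble `id`, `x`, `y`, `z`, `radius`, `type`), `latent`
#'   (nuclei x markers log-expression matrix), `markers` (list with
#'   `panel_a`, `panel_b`, `shared`), `config`.
#' @export
generate_tissue <- function(config) {
  cfg <- config
  set.seed(cfg$seed)
  n <- cfg$n_nuclei
  w <- cfg$section_thickness
  margin <- (cfg$diameter_mean + 6 * cfg$diameter_sd) / 2
  z_lo <- -margin
  z_hi <- cfg$n_sections * w + margin

  d <- rnorm(n, cfg$diameter_mean, cfg$diameter_sd)
  bad <- which(d <= 0)
  while (length(bad) > 0L) {
    d[bad] <- rnorm(length(bad), cfg$diameter_mean, cfg$diameter_sd)
    bad <- bad[d[bad] <= 0]
  }

  sep2 <- cfg$min_center_separation^2
  xs <- numeric(n); ys <- numeric(n); zs <- numeric(n)
  placed <- 0L
  tries <- 0L
  max_tries <- 200L * n
  while (placed < n) {
    tries <- tries + 1L
    if (tries > max_tries)
      abort("Could not place all nuclei under `min_center_separation`; lower the density or separation.")
    px <- runif(1, 0, cfg$slab_size[1])
    py <- runif(1, 0, cfg$slab_size[2])
    pz <- runif(1, z_lo, z_hi)
    if (placed > 0L) {
      d2 <- (xs[1:placed] - px)^2 + (ys[1:placed] - py)^2 + (zs[1:placed] - pz)^2
      if (any(d2 < sep2)) next
    }
    placed <- placed + 1L
    xs[placed] <- px; ys[placed] <- py; zs[placed] <- pz
  }

  shared <- sprintf("s%02d", seq_len(cfg$n_shared_markers))
  a_only <- sprintf("a%02d", seq_len(cfg$n_markers_panel_a - cfg$n_shared_markers))
  b_only <- sprintf("b%02d", seq_len(cfg$n_markers_panel_b - cfg$n_shared_markers))
  all_markers <- c(shared, a_only, b_only)
  types <- sample.int(cfg$n_cell_types, n, replace = TRUE)
  archetypes <- matrix(rnorm(cfg$n_cell_types * length(all_markers),
                             sd = cfg$type_separation),
                       nrow = cfg$n_cell_types,
                       dimnames = list(NULL, all_markers))
  latent <- archetypes[types, , drop = FALSE] +
    matrix(rnorm(n * length(all_markers), sd = cfg$cell_level_sd),
           nrow = n)
  rownames(latent) <- as.character(seq_len(n))

  structure(
    list(
      nuclei = tibble::tibble(id = seq_len(n), x = xs, y = ys, z = zs,
                              radius = d / 2, type = types),
      latent = latent,
      markers = list(panel_a = c(shared, a_only),
                     panel_b = c(shared, b_only),
                     shared = shared),
      config = cfg
    ),
    class = "synthetic_tissue"
  )
}

#' Slice a synthetic tissue into registered sections with ground truth
#'
#' Section `k` occupies the z-interval `((k-1) W, k W)`; a nucleus is
#' present in a section if its z-extent intersects that open interval.
#' Each present nucleus is rendered as a disk at its (x, y) center with
#' radius equal to the maximal circular cross-section of the sphere
#' within the section's z-interval; colliding disks are rasterized by
#' nearest-center assignment. Odd sections are measured with panel A,
#' even sections with panel B, so every consecutive pair shares exactly
#' the shared-marker subset. Observed intensities are
#' `exp(latent + per-section Gaussian noise)`, with the noise SD set per
#' marker to the latent SD divided by `signal_to_noise`.
#'
#' @param tissue A [generate_tissue()] result.
#' @return Object of class `serial_sections`: list with `sections` (list
#'   of [section_data()]), `ground_truth` (tibble `nucleus_id`,
#'   `section`, `cell_id`), `n_dropped` (nuclei whose in-section disk
#'   was below one pixel), `config`.
#' @export
slice_sections <- function(tissue) {
  cfg <- tissue$config
  set.seed(cfg$seed + 1L)
  w <- cfg$section_thickness
  px <- cfg$pixel_size
  ncol_px <- ceiling(cfg$slab_size[1] / px)
  nrow_px <- ceiling(cfg$slab_size[2] / px)
  nuc <- tissue$nuclei

  noise_sd <- rep(cfg$type_separation / cfg$signal_to_noise,
                  ncol(tissue$latent))
  names(noise_sd) <- colnames(tissue$latent)

  sections <- vector("list", cfg$n_sections)
  gt <- vector("list", cfg$n_sections)
  n_dropped <- 0L

  for (k in seq_len(cfg$n_sections)) {
    lo <- (k - 1) * w
    hi <- k * w
    dz <- pmax(lo - nuc$z, nuc$z - hi, 0)
    r_sec2 <- nuc$radius^2 - dz^2
    present <- nuc$z + nuc$radius > lo & nuc$z - nuc$radius < hi & r_sec2 > 0
    r_px <- sqrt(pmax(r_sec2, 0)) / px
    drop_small <- present & r_px < 1
    n_dropped <- n_dropped + sum(drop_small)
    use <- which(present & !drop_small)

    cx <- nuc$x[use] / px
    cy <- nuc$y[use] / px
    rad <- r_px[use]

    # rasterize: collect candidate pixels per disk, resolve by nearest center
    pix_list <- vector("list", length(use))
    for (i in seq_along(use)) {
      r0 <- max(0, ceiling(cy[i] - rad[i])); r1 <- min(nrow_px - 1, floor(cy[i] + rad[i]))
      c0 <- max(0, ceiling(cx[i] - rad[i])); c1 <- min(ncol_px - 1, floor(cx[i] + rad[i]))
      if (r0 > r1 || c0 > c1) next
      rr <- r0:r1; cc <- c0:c1
      rows <- rep(rr, times = length(cc))
      cols <- rep(cc, each = length(rr))
      d2 <- (rows - cy[i])^2 + (cols - cx[i])^2
      inside <- d2 <= rad[i]^2
      if (!any(inside)) next
      pix_list[[i]] <- cbind(lin = cols[inside] * nrow_px + rows[inside] + 1,
                             nucleus = use[i], d2 = d2[inside])
    }
    cand <- do.call(rbind, pix_list)
    mask <- matrix(0L, nrow_px, ncol_px)
    if (!is.null(cand) && nrow(cand) > 0L) {
      ord <- order(cand[, "lin"], cand[, "d2"])
      cand <- cand[ord, , drop = FALSE]
      first <- !duplicated(cand[, "lin"])
      winners <- cand[first, , drop = FALSE]
      kept_nuclei <- sort(unique(winners[, "nucleus"]))
      lab_of <- match(winners[, "nucleus"], kept_nuclei)
      mask[winners[, "lin"]] <- lab_of
    } else {
      kept_nuclei <- integer(0)
    }

    n_cells <- length(kept_nuclei)
    if (n_cells > 0L) {
      cent <- mask_centroids(mask)
      panel <- if (k %% 2L == 1L) tissue$markers$panel_a else tissue$markers$panel_b
      obs <- tissue$latent[kept_nuclei, panel, drop = FALSE] +
        matrix(rnorm(n_cells * length(panel)), nrow = n_cells) *
          rep(noise_sd[panel], each = n_cells)
      feats <- tibble::tibble(
        cell_id = seq_len(n_cells),
        centroid_x = unname(cent[as.character(seq_len(n_cells)), "col"]),
        centroid_y = unname(cent[as.character(seq_len(n_cells)), "row"])
      )
      for (m in panel) feats[[m]] <- exp(obs[, m])
      feats$label <- paste0("T", nuc$type[kept_nuclei])
    } else {
      feats <- tibble::tibble(cell_id = integer(), centroid_x = numeric(),
                              centroid_y = numeric(), label = character())
    }
    sections[[k]] <- section_data(mask, feats, pixel_size = px)
    gt[[k]] <- tibble::tibble(nucleus_id = kept_nuclei, section = k,
                              cell_id = seq_len(n_cells))
  }

  structure(
    list(sections = sections,
         ground_truth = dplyr::bind_rows(gt),
         n_dropped = n_dropped,
         config = cfg),
    class = "serial_sections"
  )
}

#' Ground-truth cell pairs between two sections
#'
#' @param sliced A [slice_sections()] result.
#' @param ref_section,target_section Section indices (consecutive by
#'   construction of the generator's truth).
#' @return Tibble `ref_id`, `target_id` of cells belonging to the same
#'   3D nucleus.
#' @export
ground_truth_pairs <- function(sliced, ref_section = 1, target_section = 2) {
  gt <- sliced$ground_truth
  a <- gt[gt$section == ref_section, c("nucleus_id", "cell_id")]
  b <- gt[gt$section == target_section, c("nucleus_id", "cell_id")]
  j <- dplyr::inner_join(a, b, by = "nucleus_id", suffix = c("_ref", "_target"))
  tibble::tibble(ref_id = j$cell_id_ref, target_id = j$cell_id_target)
}

#' Apply a rigid misregistration to a section
#'
#' Rotates the mask about the image center and translates it, using
#' nearest-neighbour label interpolation, and applies the same transform
#' to the table centroids. Marker intensities are unchanged. Cells whose
#' every pixel leaves the canvas (or is rounded away) are dropped from
#' the feature table.
#'
#' @param section A [section_data()].
#' @param rotation Rotation in radians (counter-clockwise about the
#'   image center).
#' @param translation Length-2 translation in pixels `c(dx, dy)`.
#' @return A transformed `section_data`.
#' @export
apply_misregistration <- function(section, rotation = 0, translation = c(0, 0)) {
  if (!is.finite(rotation) || any(!is.finite(translation)))
    abort("Transform parameters must be finite.")
  mask <- section$mask
  nr <- nrow(mask); nc <- ncol(mask)
  ctr <- c((nc - 1) / 2, (nr - 1) / 2)     # (x, y)
  cs <- cos(rotation); sn <- sin(rotation)

  # inverse map each output pixel to its source location
  out_x <- rep(0:(nc - 1), each = nr)
  out_y <- rep(0:(nr - 1), times = nc)
  qx <- out_x - translation[1] - ctr[1]
  qy <- out_y - translation[2] - ctr[2]
  sx <- round(cs * qx + sn * qy + ctr[1])
  sy <- round(-sn * qx + cs * qy + ctr[2])
  ok <- sx >= 0 & sx < nc & sy >= 0 & sy < nr
  new_mask <- matrix(0L, nr, nc)
  new_mask[cbind(out_y + 1L, out_x + 1L)[ok, , drop = FALSE]] <-
    mask[cbind(sy + 1L, sx + 1L)[ok, , drop = FALSE]]

  feats <- section$features
  fx <- feats$centroid_x - ctr[1]
  fy <- feats$centroid_y - ctr[2]
  feats$centroid_x <- cs * fx - sn * fy + ctr[1] + translation[1]
  feats$centroid_y <- sn * fx + cs * fy + ctr[2] + translation[2]

  surviving <- sort(unique(new_mask[new_mask > 0L]))
  feats <- feats[feats$cell_id %in% surviving, , drop = FALSE]
  section_data(new_mask, feats, pixel_size = section$pixel_size)
}

#' Simulate a flat cell-by-marker table with known types
#'
#' A lightweight companion to the tissue generator for harnesses that
#' need only a feature table (label-propagation validation, neighborhood
#' toys): Gaussian type archetypes plus per-cell noise, no geometry
#' beyond uniform random centroids.
#'
#' @param n_cells,n_types,n_markers Counts.
#' @param type_separation SD of archetype values (larger = more
#'   separated clusters).
#' @param noise_sd Per-cell noise SD.
#' @param field_size Side of the square field (pixels) for the random
#'   centroids.
#' @param seed Integer seed.
#' @return Tibble `cell_id`, `centroid_x`, `centroid_y`, markers
#'   `m01...`, `label`.
#' @export
simulate_marker_table <- function(n_cells, n_types = 5, n_markers = 24,
                                  type_separation = 4, noise_sd = 1,
                                  field_size = 500, seed = 1) {
  set.seed(seed)
  markers <- sprintf("m%02d", seq_len(n_markers))
  types <- sample.int(n_types, n_cells, replace = TRUE)
  arch <- matrix(rnorm(n_types * n_markers, sd = type_separation),
                 nrow = n_types)
  x <- arch[types, , drop = FALSE] +
    matrix(rnorm(n_cells * n_markers, sd = noise_sd), nrow = n_cells)
  out <- tibble::tibble(cell_id = seq_len(n_cells),
                        centroid_x = runif(n_cells, 0, field_size),
                        centroid_y = runif(n_cells, 0, field_size))
  for (j in seq_len(n_markers)) out[[markers[j]]] <- x[, j]
  out$label <- paste0("T", types)
  out
}
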