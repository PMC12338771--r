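# shared fixtures, all built in code

# small synthetic serial-section pair
make_sections <- function(n_nuclei = 200, slab = c(180, 180), seed = 1, ...) {
  cfg <- synthetic_tissue_config(n_nuclei = n_nuclei, slab_size = slab,
                                 seed = seed, ...)
  slice_sections(generate_tissue(cfg))
}

# section_data from a bare mask; marker values supplied per label (rows)
section_from_mask <- function(mask, marker_values = NULL, pixel_size = 1) {
  reg <- extract_regions(mask)
  feats <- tibble::tibble(cell_id = reg$label,
                          centroid_x = reg$centroid_col,
                          centroid_y = reg$centroid_row)
  if (!is.null(marker_values)) {
    stopifnot(nrow(marker_values) == nrow(reg))
    for (j in seq_len(ncol(marker_values)))
      feats[[colnames(marker_values)[j]]] <- marker_values[, j]
  }
  section_data(mask, feats, pixel_size = pixel_size)
}

# hand-buildable cost matrix for solver tests (Inf = infeasible)
cost_matrix_from <- function(cc) {
  structure(
    list(cost = ifelse(is.finite(cc), cc, 0),
         feasible = is.finite(cc),
         undefined = matrix(FALSE, nrow(cc), ncol(cc)),
         dist_um = matrix(0, nrow(cc), ncol(cc)),
         ref_ids = seq_len(nrow(cc)),
         target_ids = seq_len(ncol(cc)),
         radius_um = Inf),
    class = "cost_matrix")
}

# exhaustive minimum-cost maximum-cardinality assignment (oracle)
brute_force_lsa <- function(cc) {
  n <- nrow(cc); m <- ncol(cc)
  best_card <- -1L; best_cost <- Inf
  rec <- function(row, used, card, cost) {
    if (row > n) {
      if (card > best_card ||
          (card == best_card && cost < best_cost - 1e-12)) {
        best_card <<- card; best_cost <<- cost
      }
      return(invisible())
    }
    rec(row + 1L, used, card, cost)
    for (j in seq_len(m)) {
      if (!used[j] && is.finite(cc[row, j])) {
        used[j] <- TRUE
        rec(row + 1L, used, card + 1L, cost + cc[row, j])
        used[j] <- FALSE
      }
    }
  }
  rec(1L, rep(FALSE, m), 0L, 0)
  list(cardinality = best_card, cost = best_cost)
}

# regular lattice of boundary-spanning nuclei: every cell appears in both
# sections with a concentric footprint, cells far apart in XY
lattice_sections <- function(nx = 4, ny = 4, spacing_px = 20, disk_px = 5,
                             n_markers = 6, noise_sd = 0.1, seed = 1) {
  set.seed(seed)
  dim_px <- spacing_px * (nx + 1)
  centers <- expand.grid(cx = spacing_px * seq_len(nx),
                         cy = spacing_px * seq_len(ny))
  n <- nrow(centers)
  draw_mask <- function(radii) {
    mask <- matrix(0L, dim_px, dim_px)
    for (i in seq_len(n)) {
      rr <- (centers$cy[i] - radii[i]):(centers$cy[i] + radii[i])
      cc <- (centers$cx[i] - radii[i]):(centers$cx[i] + radii[i])
      grid <- expand.grid(r = rr, c = cc)
      d2 <- (grid$r - centers$cy[i])^2 + (grid$c - centers$cx[i])^2
      grid <- grid[d2 <= radii[i]^2, ]
      mask[cbind(grid$r + 1L, grid$c + 1L)] <- i
    }
    mask
  }
  latent <- matrix(rnorm(n * n_markers, sd = 2), n,
                   dimnames = list(NULL, sprintf("s%02d", seq_len(n_markers))))
  obs <- function() exp(latent + rnorm(length(latent), sd = noise_sd))
  m1 <- draw_mask(rep(disk_px, n))
  m2 <- draw_mask(rep(disk_px - 1, n))
  list(ref = section_from_mask(m1, obs()),
       target = section_from_mask(m2, obs()))
}
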