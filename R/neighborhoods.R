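#' Cell-type counts in the neighbourhood of anchor cells
#'
#' For each anchor, counts the cell types among the cells whose centroid
#' lies within `radius_um` (closed ball, micrometres via `pixel_size`).
#' The anchor itself is excluded from its own neighbourhood by default
#' ("neighbouring" cells read literally); set `include_anchor = TRUE` to
#' include it, which shifts every row by one count of the anchor's own
#' type.
#'
#' @param cells Tibble with `cell_id`, `centroid_x`, `centroid_y`,
#'   `label` (pixel coordinates).
#' @param anchor_ids Cell ids to use as anchors; must be present in
#'   `cells`.
#' @param radius_um Neighbourhood radius in micrometres (default 30).
#' @param pixel_size Micrometres per pixel.
#' @param include_anchor Include the anchor cell in its own counts.
#' @return Integer matrix, anchors x cell types; rownames are anchor
#'   ids, colnames the sorted type labels.
#' @export
neighborhood_counts <- function(cells, anchor_ids, radius_um = 30,
                                pixel_size = 1, include_anchor = FALSE) {
  if (radius_um <= 0) abort("`radius_um` must be positive.")
  if (!"label" %in% names(cells)) abort("`cells` needs a `label` column.")
  a_idx <- match(anchor_ids, cells$cell_id)
  if (anyNA(a_idx))
    abort("`anchor_ids` contains ids absent from `cells`.")
  types <- sort(unique(as.character(cells$label)))
  r_px2 <- (radius_um / pixel_size)^2
  counts <- matrix(0L, length(anchor_ids), length(types),
                   dimnames = list(as.character(anchor_ids), types))
  lab <- factor(as.character(cells$label), levels = types)
  for (i in seq_along(a_idx)) {
    d2 <- (cells$centroid_x - cells$centroid_x[a_idx[i]])^2 +
      (cells$centroid_y - cells$centroid_y[a_idx[i]])^2
    inb <- d2 <= r_px2
    if (!include_anchor) inb[a_idx[i]] <- FALSE
    counts[i, ] <- tabulate(lab[inb], nbins = length(types))
  }
  counts
}

#' Cluster per-anchor neighbourhood compositions into recurrent
#' neighbourhoods
#'
#' Row-normalizes each panel's anchor-by-type count matrix to
#' proportions, concatenates the two panel blocks along the feature
#' axis, and clusters the rows with seeded k-means (10 restarts).
#' Anchors with zero neighbours in either panel are flagged and
#' excluded from clustering. An inertia (within-cluster sum of squares)
#' curve over `elbow_range` supports choosing the cluster number.
#'
#' @param counts_a,counts_b Anchor-by-type count matrices from
#'   [neighborhood_counts()], same anchors (rownames) in both.
#' @param n_clusters Number of recurrent neighbourhoods (default 15).
#' @param elbow_range Optional integer vector of k values for the
#'   inertia curve (e.g. `5:50`).
#' @param seed Integer seed.
#' @param nstart k-means restarts.
#' @return Object of class `rcn`: list with `proportions` (anchors x
#'   2*types block matrix), `assignments` (tibble `anchor_id`,
#'   `cluster`), `centers`, `inertia` (tibble `k`, `tot_withinss`),
#'   `excluded` (anchor ids with an empty neighbourhood).
#' @export
rcn_cluster <- function(counts_a, counts_b, n_clusters = 15,
                        elbow_range = NULL, seed = 1, nstart = 10) {
  if (!identical(rownames(counts_a), rownames(counts_b)))
    abort("The two panels' count matrices must have identical anchors.")
  rs_a <- rowSums(counts_a)
  rs_b <- rowSums(counts_b)
  keep <- rs_a > 0 & rs_b > 0
  excluded <- rownames(counts_a)[!keep]
  if (sum(keep) < 2L) abort("Fewer than 2 anchors with non-empty neighbourhoods.")
  prop_a <- counts_a[keep, , drop = FALSE] / rs_a[keep]
  prop_b <- counts_b[keep, , drop = FALSE] / rs_b[keep]
  colnames(prop_a) <- paste0("A:", colnames(prop_a))
  colnames(prop_b) <- paste0("B:", colnames(prop_b))
  x <- cbind(prop_a, prop_b)

  ux <- unique(x)
  k_eff <- min(n_clusters, nrow(ux))
  if (k_eff < n_clusters)
    warn(sprintf("Only %d distinct composition rows; clustering with k = %d.",
                 nrow(ux), k_eff))
  set.seed(seed)
  km <- kmeans_or_trivial(ux, k_eff, nstart)
  row_key <- apply(x, 1L, paste, collapse = "\r")
  ux_key <- apply(ux, 1L, paste, collapse = "\r")
  assign_all <- km$cluster[match(row_key, ux_key)]

  inertia <- NULL
  if (!is.null(elbow_range)) {
    ks <- elbow_range[elbow_range >= 1 & elbow_range <= nrow(ux)]
    inertia <- purrr::map_dfr(ks, function(k) {
      set.seed(seed)
      tibble::tibble(k = k,
                     tot_withinss = kmeans_or_trivial(ux, k, nstart)$tot.withinss)
    })
  }

  structure(
    list(proportions = x,
         assignments = tibble::tibble(anchor_id = rownames(x),
                                      cluster = unname(assign_all)),
         centers = km$centers,
         inertia = inertia,
         excluded = excluded),
    class = "rcn"
  )
}

# stats::kmeans requires k < nrow; with k == nrow each distinct row is
# its own cluster and the partition is exact
kmeans_or_trivial <- function(x, k, nstart) {
  if (k >= nrow(x)) {
    return(list(cluster = seq_len(nrow(x)), centers = x, tot.withinss = 0))
  }
  kmeans(x, centers = k, nstart = nstart, iter.max = 100)
}

#' @export
print.rcn <- function(x, ...) {
  cat(sprintf("recurrent cellular neighbourhoods: %d anchors, %d clusters (%d excluded)\n",
              nrow(x$proportions), nrow(x$centers), length(x$excluded)))
  invisible(x)
}

#' @export
tidy.rcn <- function(x, ...) x$assignments

#' @export
glance.rcn <- function(x, ...) {
  tibble::tibble(n_anchors = nrow(x$proportions),
                 n_clusters = nrow(x$centers),
                 n_excluded = length(x$excluded))
}

#' @export
autoplot.rcn <- function(object, ...) {
  df <- tibble::as_tibble(object$centers, rownames = "cluster")
  df <- tidyr::pivot_longer(df, -"cluster", names_to = "feature",
                            values_to = "proportion")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$feature, y = .data$cluster,
                                   fill = .data$proportion)) +
    ggplot2::geom_tile() +
    ggplot2::labs(x = "panel : cell type", y = "RCN") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}
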