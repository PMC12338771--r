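#' Propagate cell-type labels to unlabeled cells by k-NN majority vote
#'
#' Each unlabeled cell receives the majority label of its `k` nearest
#' labeled cells under Euclidean distance on the given markers (default
#' `k = 10`, unweighted votes). A vote tie is broken deterministically
#' by the nearest neighbour carrying one of the tied labels.
#'
#' @param labeled Feature table with a `label` column (the combined-panel
#'   annotations of the matched cells).
#' @param unlabeled Feature table to annotate.
#' @param markers Marker columns to use; must be present in both tables.
#'   Defaults to the marker columns shared by the two tables.
#' @param k Neighbour count (>= 1, at most `nrow(labeled)`).
#' @param transform `"none"` or `"log1p_zscore"` (log1p then z-score,
#'   fitted on the pooled rows of both tables).
#' @return Tibble `cell_id`, `label` for the unlabeled cells.
#' @export
propagate_labels <- function(labeled, unlabeled, markers = NULL, k = 10,
                             transform = c("none", "log1p_zscore")) {
  transform <- match.arg(transform)
  if (!"label" %in% names(labeled)) abort("`labeled` needs a `label` column.")
  markers <- markers %||% intersect(marker_columns(labeled),
                                    marker_columns(unlabeled))
  if (length(markers) == 0L ||
      !all(markers %in% names(labeled)) || !all(markers %in% names(unlabeled)))
    abort("Marker columns do not match between the two tables.")
  if (k < 1 || k > nrow(labeled))
    abort(sprintf("`k` = %d but only %d labeled cells.", k, nrow(labeled)))

  xl <- as.matrix(labeled[, markers, drop = FALSE])
  xu <- as.matrix(unlabeled[, markers, drop = FALSE])
  if (transform == "log1p_zscore") {
    pooled <- log1p(rbind(xl, xu))
    mu <- colMeans(pooled)
    sg <- apply(pooled, 2L, sd)
    sg[sg == 0] <- 1
    xl <- sweep(sweep(log1p(xl), 2L, mu), 2L, sg, "/")
    xu <- sweep(sweep(log1p(xu), 2L, mu), 2L, sg, "/")
  }
  tibble::tibble(cell_id = unlabeled$cell_id,
                 label = knn_vote(xl, labeled$label, xu, k))
}

# chunked Euclidean k-NN with deterministic, distance-respecting tie rule
knn_vote <- function(train_x, train_lab, test_x, k) {
  train_lab <- as.character(train_lab)
  t2 <- rowSums(train_x^2)
  n_test <- nrow(test_x)
  out <- character(n_test)
  chunk <- max(1L, floor(2e7 / max(1L, nrow(train_x))))
  for (start in seq(1L, n_test, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n_test)
    xs <- test_x[idx, , drop = FALSE]
    d2 <- outer(rowSums(xs^2), t2, "+") - 2 * tcrossprod(xs, train_x)
    for (r in seq_along(idx)) {
      nn <- order(d2[r, ])[seq_len(k)]
      labs <- train_lab[nn]
      tab <- table(labs)
      winners <- names(tab)[tab == max(tab)]
      out[idx[r]] <- if (length(winners) == 1L) winners else
        labs[which(labs %in% winners)[1L]]
    }
  }
  out
}

#' Random-panel validation of label propagation
#'
#' The single-slide harness for label propagation: cells with known
#' ground-truth labels are split into "tracked" and "untracked" subsets
#' across a range of proportions; for each proportion and each random
#' marker panel, a k-NN classifier fitted on the tracked cells predicts
#' the untracked cells, and a class-weighted F1 score is computed on a
#' random subsample of the predictions. At proportion 1.0 a random
#' sample of the tracked cells themselves is predicted and scored,
#' defining the performance ceiling.
#'
#' @param features Feature table (marker columns are all non-id,
#'   non-centroid, non-label numeric columns).
#' @param truth_labels Ground-truth label per row (>= 2 classes). Any
#'   label vector may be supplied; the synthetic generator's known types
#'   play this role in tests.
#' @param proportions Tracked proportions in (0, 1\] (default 0.1-1.0 by
#'   0.1).
#' @param n_panels Random marker panels per proportion (default 1000).
#' @param panel_size Markers per panel (default half the markers,
#'   mirroring two panels that share half their markers).
#' @param eval_sample_size Predictions sampled for scoring (default
#'   `min(5000, n_untracked)`).
#' @param k Neighbour count for the classifier.
#' @param transform Passed to [propagate_labels()].
#' @param seed Integer seed; splits, panels and subsamples are all
#'   deterministic given the seed.
#' @return Tibble of class `panel_validation`: `proportion`, `panel`,
#'   `f1` (class-weighted), `flagged` (a truth class was absent from the
#'   tracked split).
#' @export
validate_propagation <- function(features, truth_labels,
                                 proportions = seq(0.1, 1, by = 0.1),
                                 n_panels = 1000, panel_size = NULL,
                                 eval_sample_size = NULL, k = 10,
                                 transform = c("none", "log1p_zscore"),
                                 seed = 1) {
  transform <- match.arg(transform)
  truth_labels <- as.character(truth_labels)
  if (length(truth_labels) != nrow(features))
    abort("`truth_labels` must cover every row of `features`.")
  if (length(unique(truth_labels)) < 2L)
    abort("Need at least 2 ground-truth classes.")
  if (any(proportions <= 0 | proportions > 1))
    abort("`proportions` must lie in (0, 1].")
  markers <- marker_columns(features)
  panel_size <- panel_size %||% floor(length(markers) / 2)
  if (panel_size > length(markers))
    abort("`panel_size` exceeds the number of markers.")
  x <- as.matrix(features[, markers, drop = FALSE])
  if (transform == "log1p_zscore") {
    x <- log1p(x)
    x <- sweep(x, 2L, colMeans(x))
    sg <- apply(x, 2L, sd); sg[sg == 0] <- 1
    x <- sweep(x, 2L, sg, "/")
  }
  n <- nrow(x)

  set.seed(seed)
  panels <- lapply(seq_len(n_panels),
                   function(i) sample(markers, panel_size))

  out <- purrr::map_dfr(proportions, function(p) {
    purrr::map_dfr(seq_len(n_panels), function(pi) {
      cols <- panels[[pi]]
      if (p < 1) {
        tracked <- sample.int(n, round(p * n))
        untracked <- setdiff(seq_len(n), tracked)
      } else {
        tracked <- seq_len(n)
        untracked <- seq_len(n)
      }
      es <- eval_sample_size %||% min(5000L, length(untracked))
      eval_idx <- if (length(untracked) > es) sample(untracked, es) else untracked
      kk <- min(k, length(tracked))
      pred <- knn_vote(x[tracked, cols, drop = FALSE],
                       truth_labels[tracked],
                       x[eval_idx, cols, drop = FALSE], kk)
      tibble::tibble(
        proportion = p, panel = pi,
        f1 = weighted_f1(truth_labels[eval_idx], pred),
        flagged = length(unique(truth_labels[tracked])) <
          length(unique(truth_labels)))
    })
  })
  class(out) <- c("panel_validation", class(out))
  out
}

# class-weighted F1: per-class F1 averaged with weights = true support
weighted_f1 <- function(truth, pred) {
  classes <- unique(truth)
  f1s <- vapply(classes, function(cl) {
    tp <- sum(truth == cl & pred == cl)
    fp <- sum(truth != cl & pred == cl)
    fn <- sum(truth == cl & pred != cl)
    if (2 * tp + fp + fn == 0) return(0)
    2 * tp / (2 * tp + fp + fn)
  }, numeric(1))
  support <- vapply(classes, function(cl) sum(truth == cl), numeric(1))
  sum(f1s * support) / sum(support)
}

#' @export
autoplot.panel_validation <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = factor(.data$proportion),
                                       y = .data$f1)) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(x = "tracked proportion", y = "weighted F1")
}

#' @export
glance.panel_validation <- function(x, ...) {
  dplyr::summarise(dplyr::group_by(x, .data$proportion),
                   mean_f1 = mean(.data$f1), sd_f1 = sd(.data$f1),
                   n_panels = dplyr::n(), .groups = "drop")
}
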