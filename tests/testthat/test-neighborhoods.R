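test_that("the 5-cell toy neighbourhood counts match hand arithmetic", {
  # anchor at the origin; type X at 10 and 25 um, type Y at 29 and 35 um
  cells <- tibble::tibble(
    cell_id = 1:5,
    centroid_x = c(0, 10, 25, 29, 35),
    centroid_y = 0,
    label = c("X", "X", "X", "Y", "Y"))
  counts <- neighborhood_counts(cells, anchor_ids = 1L, radius_um = 30,
                                pixel_size = 1)
  expect_equal(counts["1", "X"], 2L)   # anchor itself excluded
  expect_equal(counts["1", "Y"], 1L)   # 29 <= 30 (closed ball), 35 outside

  with_anchor <- neighborhood_counts(cells, 1L, 30, include_anchor = TRUE)
  expect_equal(with_anchor["1", "X"], 3L)

  # micrometre conversion: same table at 0.5 um/px halves every distance
  scaled <- neighborhood_counts(cells, 1L, 15, pixel_size = 0.5)
  expect_equal(scaled["1", ], counts["1", ])

  tiny <- neighborhood_counts(cells, 1L, 1e-9)
  expect_equal(sum(tiny), 0L)

  one_type <- neighborhood_counts(dplyr::mutate(cells, label = "X"), 1L, 30)
  expect_equal(colnames(one_type), "X")
  expect_error(neighborhood_counts(cells, 99L, 30), "absent")
})

test_that("row normalization and two-block recovery behave as designed", {
  counts <- matrix(c(2L, 2L, 0L), 1, dimnames = list("1", c("a", "b", "c")))
  r <- rcn_cluster(rbind(counts, counts, counts,
                         matrix(c(0L, 1L, 3L), 1, dimnames = list("2", NULL)),
                         matrix(c(0L, 1L, 3L), 1, dimnames = list("3", NULL)),
                         matrix(c(0L, 1L, 3L), 1, dimnames = list("4", NULL))),
                   rbind(counts, counts, counts,
                         matrix(c(0L, 1L, 3L), 1, dimnames = list("2", NULL)),
                         matrix(c(0L, 1L, 3L), 1, dimnames = list("3", NULL)),
                         matrix(c(0L, 1L, 3L), 1, dimnames = list("4", NULL))),
                   n_clusters = 2, seed = 1)
  expect_equal(unname(r$proportions[1, 1:3]), c(0.5, 0.5, 0))
  # each panel block row sums to 1
  expect_true(all(abs(rowSums(r$proportions[, 1:3]) - 1) < 1e-12))
  expect_true(all(abs(rowSums(r$proportions[, 4:6]) - 1) < 1e-12))

  # two spatially segregated types form two exact clusters at k = 2
  set.seed(2)
  n <- 50
  cells <- tibble::tibble(
    cell_id = 1:(2 * n),
    centroid_x = c(runif(n, 0, 40), runif(n, 200, 240)),
    centroid_y = runif(2 * n, 0, 40),
    label = rep(c("X", "Y"), each = n))
  ca <- neighborhood_counts(cells, cells$cell_id, radius_um = 50)
  r2 <- rcn_cluster(ca, ca, n_clusters = 2, seed = 1)
  # label-permutation-invariant exact recovery of the two blocks
  cl <- r2$assignments$cluster[match(as.character(cells$cell_id),
                                     r2$assignments$anchor_id)]
  expect_equal(length(unique(cl[1:n])), 1L)
  expect_equal(length(unique(cl[(n + 1):(2 * n)])), 1L)
  expect_false(cl[1] == cl[n + 1])
})

test_that("identical composition rows collapse to one effective cluster", {
  counts <- matrix(rep(c(1L, 1L), 8), 8, 2, byrow = TRUE,
                   dimnames = list(as.character(1:8), c("a", "b")))
  expect_warning(r <- rcn_cluster(counts, counts, n_clusters = 3, seed = 1),
                 "distinct")
  expect_equal(length(unique(r$assignments$cluster)), 1L)
})

test_that("zero-neighbour anchors are excluded and flagged", {
  counts <- matrix(c(3L, 1L,
                     0L, 0L,
                     1L, 3L), 3, 2, byrow = TRUE,
                   dimnames = list(as.character(1:3), c("a", "b")))
  r <- rcn_cluster(counts, counts, n_clusters = 2, seed = 1)
  expect_equal(r$excluded, "2")
  expect_equal(nrow(r$proportions), 2L)
  expect_error(rcn_cluster(counts, counts[c(2, 1, 3), ]), "identical")
})

test_that("cluster assignments are invariant to row order up to relabeling", {
  skip_if_not_installed("mclust")
  set.seed(9)
  counts <- matrix(rpois(60 * 4, lambda = 3), 60, 4,
                   dimnames = list(as.character(1:60), letters[1:4]))
  counts[counts == 0] <- 1L
  r1 <- rcn_cluster(counts, counts, n_clusters = 4, seed = 7)
  perm <- sample(1:60)
  r2 <- rcn_cluster(counts[perm, ], counts[perm, ], n_clusters = 4, seed = 7)
  a1 <- r1$assignments$cluster[match(as.character(1:60),
                                     r1$assignments$anchor_id)]
  a2 <- r2$assignments$cluster[match(as.character(1:60),
                                     r2$assignments$anchor_id)]
  expect_equal(mclust::adjustedRandIndex(a1, a2), 1.0)
})

test_that("the inertia curve is emitted over the requested range", {
  set.seed(3)
  counts <- matrix(rpois(40 * 3, 4) + 1L, 40, 3,
                   dimnames = list(as.character(1:40), c("a", "b", "c")))
  r <- rcn_cluster(counts, counts, n_clusters = 3, elbow_range = 2:6, seed = 2)
  expect_equal(r$inertia$k, 2:6)
  expect_true(all(diff(r$inertia$tot_withinss) <= 1e-8))
})
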