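test_that("cost matrix entries delegate to the pair cost and feasibility to distances", {
  mk <- c("m1", "m2", "m3", "m4")
  set.seed(41)
  mask1 <- matrix(0L, 20, 20); mask2 <- matrix(0L, 20, 20)
  pos <- cbind(c(3, 9, 15), c(4, 12, 7))
  for (i in 1:3) { mask1[pos[i, 1], pos[i, 2]] <- i; mask2[pos[i, 1], pos[i, 2]] <- i }
  vals1 <- matrix(rnorm(12), 3, dimnames = list(NULL, mk))
  vals2 <- matrix(rnorm(12), 3, dimnames = list(NULL, mk))
  ref <- section_from_mask(mask1, vals1, pixel_size = 2)
  tgt <- section_from_mask(mask2, vals2, pixel_size = 2)

  cm <- build_cost_matrix(ref, tgt, mk, radius_um = Inf)
  for (i in 1:3) for (j in 1:3) {
    expect_equal(cm$cost[i, j],
                 as.numeric(spearman_pair_cost(vals1[i, ], vals2[j, ])),
                 tolerance = 1e-12)
  }
  # feasibility pattern equals brute-force thresholded centroid distances
  for (radius in c(5, 12, 25)) {
    cmr <- build_cost_matrix(ref, tgt, mk, radius_um = radius)
    for (i in 1:3) for (j in 1:3) {
      d <- 2 * sqrt(sum((pos[i, ] - pos[j, ])^2))   # pixel_size = 2
      expect_equal(cmr$feasible[i, j], d <= radius)
    }
  }
  # a tiny radius with coincident centroids keeps only the self-positions
  cm0 <- build_cost_matrix(ref, tgt, mk, radius_um = 1e-9)
  expect_equal(cm0$feasible, diag(3) == 1, ignore_attr = TRUE)
})

test_that("constrained LSA solves the printed 3x3 examples", {
  cc <- matrix(c(0.1, 0.9, 0.8,
                 0.9, 0.2, 0.7,
                 0.8, 0.7, 0.3), 3, 3, byrow = TRUE)
  ms <- constrained_lsa(cost_matrix_from(cc))
  expect_equal(ms$target_id[order(ms$ref_id)], 1:3)
  expect_equal(sum(ms$cost), 0.6)

  cc2 <- cc; cc2[1, 1] <- Inf
  ms2 <- constrained_lsa(cost_matrix_from(cc2))
  oracle <- brute_force_lsa(cc2)
  expect_equal(nrow(ms2), oracle$cardinality)
  expect_equal(sum(ms2$cost), oracle$cost)  # = 0.8 + 0.2 + 0.8 by enumeration

  ident <- matrix(2, 3, 3); diag(ident) <- 0
  ms3 <- constrained_lsa(cost_matrix_from(ident))
  expect_equal(ms3$target_id[order(ms3$ref_id)], 1:3)
  expect_equal(sum(ms3$cost), 0)
})

test_that("constrained LSA equals exhaustive enumeration on random instances", {
  set.seed(91)
  for (i in 1:60) {
    n <- sample(1:6, 1); m <- sample(1:6, 1)
    cc <- matrix(round(runif(n * m), 3), n, m)
    if (runif(1) < 0.6) cc[matrix(runif(n * m) < 0.4, n, m)] <- Inf
    if (!any(is.finite(cc))) next
    ms <- constrained_lsa(cost_matrix_from(cc))
    oracle <- brute_force_lsa(cc)
    expect_equal(nrow(ms), oracle$cardinality)
    expect_equal(sum(ms$cost), oracle$cost, tolerance = 1e-9)
    expect_true(all(is.finite(ms$cost)))   # no sentinel in the solution
  }
})

test_that("coexist matches identical sections to themselves at cost 0", {
  st <- make_sections(n_nuclei = 60, slab = c(100, 100), seed = 12)
  s1 <- st$sections[[1]]
  ms <- coexist_match(s1, s1)
  expect_equal(nrow(ms), nrow(s1$features))
  expect_equal(ms$ref_id, ms$target_id)
  expect_true(all(abs(ms$cost) < 1e-12))
})

test_that("coexist overrides an overlap-majority vote when the markers disagree", {
  # ref cell 1 overlaps target 2 by 3 px (anti-correlated markers, cost 2)
  # and target 3 by 1 px (correlated markers, cost 0)
  ref <- matrix(c(1L, 1L, 1L, 1L, 0L, 0L), nrow = 1)
  tgt <- matrix(c(2L, 2L, 2L, 3L, 3L, 3L), nrow = 1)
  ref_s <- section_from_mask(ref, matrix(c(1, 2, 3, 4), 1,
                                         dimnames = list(NULL, paste0("s", 1:4))))
  tgt_s <- section_from_mask(tgt, matrix(c(4, 3, 2, 1,
                                           2, 3, 4, 5), 2, byrow = TRUE,
                                         dimnames = list(NULL, paste0("s", 1:4))))
  spatial <- track_cells(ref_s, tgt_s)
  expect_equal(spatial$target_id, 2L)
  combined <- coexist_match(ref_s, tgt_s)
  expect_equal(combined$target_id, 3L)
  expect_equal(combined$cost, 0)
})

test_that("coexist output is bijective and invariant to swapping the sections", {
  for (seed in c(3, 8, 21)) {
    st <- make_sections(n_nuclei = 150, slab = c(160, 160), seed = seed)
    fwd <- coexist_match(st$sections[[1]], st$sections[[2]])
    rev <- coexist_match(st$sections[[2]], st$sections[[1]])
    expect_equal(anyDuplicated(fwd$ref_id), 0L)
    expect_equal(anyDuplicated(fwd$target_id), 0L)
    expect_equal(sort(paste(fwd$ref_id, fwd$target_id)),
                 sort(paste(rev$target_id, rev$ref_id)))
  }
})

test_that("coexist considers exactly the tracking candidate sets", {
  st <- make_sections(n_nuclei = 100, slab = c(130, 130), seed = 14)
  s1 <- st$sections[[1]]; s2 <- st$sections[[2]]
  cand <- coexist:::overlap_candidates(s1, s2)
  # independent brute-force candidate computation from the masks
  for (lab in sample(s1$features$cell_id, 10)) {
    under <- s2$mask[s1$mask == lab]
    expected <- cand[[as.character(lab)]]
    if (is.null(expected)) expected <- integer(0)
    expect_equal(sort(unique(under[under > 0])), sort(expected),
                 ignore_attr = TRUE)
  }
  # every matched pair (from either matcher) is within the candidate sets
  for (ms in list(track_cells(s1, s2), coexist_match(s1, s2))) {
    ok <- mapply(function(a, b) b %in% cand[[as.character(a)]],
                 ms$ref_id, ms$target_id)
    expect_true(all(ok))
  }
})

test_that("track, coexist and small-radius LSA agree on well-separated lattices", {
  lt <- lattice_sections(seed = 6)
  truth <- tibble::tibble(ref_id = lt$ref$features$cell_id,
                          target_id = lt$ref$features$cell_id)
  tr <- track_cells(lt$ref, lt$target)
  cx <- coexist_match(lt$ref, lt$target)
  cm <- build_cost_matrix(lt$ref, lt$target, radius_um = 5)
  la <- constrained_lsa(cm)
  for (ms in list(tr, cx, la)) {
    expect_equal(sort(paste(ms$ref_id, ms$target_id)),
                 sort(paste(truth$ref_id, truth$target_id)))
  }
})

test_that("degrading to tracking without shared markers reproduces track_cells", {
  st <- make_sections(n_nuclei = 80, slab = c(120, 120), seed = 23)
  s1 <- st$sections[[1]]; s2 <- st$sections[[2]]
  ms <- coexist_match(s1, s2, markers = character(0))
  tr <- track_cells(s1, s2)
  expect_equal(sort(paste(ms$ref_id, ms$target_id)),
               sort(paste(tr$ref_id, tr$target_id)))
})
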