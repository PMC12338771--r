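test_that("k = 1 propagation equals a brute-force nearest-neighbour scan", {
  set.seed(61)
  labeled <- tibble::tibble(cell_id = 1:50, centroid_x = 0, centroid_y = 0,
                            m1 = rnorm(50), m2 = rnorm(50),
                            label = sample(c("A", "B", "C"), 50, TRUE))
  unlabeled <- tibble::tibble(cell_id = 1:30, centroid_x = 0, centroid_y = 0,
                              m1 = rnorm(30), m2 = rnorm(30))
  got <- propagate_labels(labeled, unlabeled, c("m1", "m2"), k = 1)
  for (i in 1:30) {
    d <- (labeled$m1 - unlabeled$m1[i])^2 + (labeled$m2 - unlabeled$m2[i])^2
    expect_equal(got$label[i], labeled$label[which.min(d)])
  }
})

test_that("a duplicated row inside a homogeneous cluster inherits its label", {
  labeled <- tibble::tibble(cell_id = 1:20, centroid_x = 0, centroid_y = 0,
                            m1 = c(rnorm(10, 0, 0.1), rnorm(10, 50, 0.1)),
                            label = rep(c("lo", "hi"), each = 10))
  unlabeled <- tibble::tibble(cell_id = 1L, centroid_x = 0, centroid_y = 0,
                              m1 = labeled$m1[3])
  expect_equal(propagate_labels(labeled, unlabeled, "m1", k = 5)$label, "lo")
})

test_that("well-separated Gaussian clusters propagate almost perfectly", {
  set.seed(62)
  n <- 1000
  cl <- sample(1:2, n, TRUE)
  tab <- tibble::tibble(cell_id = 1:n, centroid_x = 0, centroid_y = 0,
                        m1 = rnorm(n, mean = 10 * cl), m2 = rnorm(n),
                        label = paste0("C", cl))
  lab_idx <- sample.int(n, round(0.6 * n))
  got <- propagate_labels(tab[lab_idx, ], tab[-lab_idx, ], c("m1", "m2"),
                          k = 10)
  truth <- tab$label[-lab_idx]
  tp <- sum(got$label == truth)
  f1 <- 2 * tp / (2 * tp + sum(got$label != truth) + 0)
  expect_gte(mean(got$label == truth), 0.99)
  expect_gte(f1, 0.99)
})

test_that("propagation rejects bad inputs and is deterministic", {
  labeled <- tibble::tibble(cell_id = 1:5, centroid_x = 0, centroid_y = 0,
                            m1 = rnorm(5), label = letters[1:5])
  unlabeled <- tibble::tibble(cell_id = 1:3, centroid_x = 0, centroid_y = 0,
                              m1 = rnorm(3))
  expect_error(propagate_labels(labeled, unlabeled, "m1", k = 6), "labeled")
  expect_error(propagate_labels(labeled, unlabeled, "mX"), "match")
  a <- propagate_labels(labeled, unlabeled, "m1", k = 3)
  b <- propagate_labels(labeled, unlabeled, "m1", k = 3)
  expect_identical(a, b)
})

test_that("panel validation improves with tracking proportion and hits its ceiling", {
  tab <- simulate_marker_table(1200, n_types = 5, n_markers = 24,
                               type_separation = 1, seed = 70)
  res <- validate_propagation(tab, tab$label, proportions = c(0.2, 0.8),
                              n_panels = 12, seed = 7)
  g <- glance(res)
  expect_gte(g$mean_f1[g$proportion == 0.8], g$mean_f1[g$proportion == 0.2])

  # full panel, full tracking, well-separated clusters: self-consistency ceiling
  easy <- simulate_marker_table(600, n_types = 5, n_markers = 24,
                                type_separation = 4, seed = 71)
  ceiling_res <- validate_propagation(easy, easy$label, proportions = 1.0,
                                      n_panels = 1, panel_size = 24, seed = 7)
  expect_gte(ceiling_res$f1, 0.99)

  expect_error(validate_propagation(tab, rep("x", nrow(tab))), "2")
  expect_error(validate_propagation(tab, tab$label, proportions = c(0, 0.5)),
               "proportions")
})

test_that("panel-level proportion-F1 correlations are predominantly positive", {
  tab <- simulate_marker_table(900, n_types = 5, n_markers = 24,
                               type_separation = 1, seed = 72)
  res <- validate_propagation(tab, tab$label,
                              proportions = c(0.2, 0.5, 0.8),
                              n_panels = 12, seed = 9)
  cors <- vapply(split(res, res$panel),
                 function(d) cor(d$proportion, d$f1), numeric(1))
  expect_gt(mean(cors > 0, na.rm = TRUE), 0.5)
})

test_that("propagated composition stays close to the truth when F1 is high", {
  tab <- simulate_marker_table(1500, n_types = 4, n_markers = 24,
                               type_separation = 2, seed = 73)
  set.seed(73)
  lab_idx <- sample.int(nrow(tab), round(0.6 * nrow(tab)))
  got <- propagate_labels(tab[lab_idx, ], tab[-lab_idx, ], k = 10)
  truth <- tab$label[-lab_idx]
  f1 <- coexist:::weighted_f1(truth, got$label)
  expect_gte(f1, 0.9)
  comp_t <- table(factor(truth)) / length(truth)
  comp_p <- table(factor(got$label, levels = levels(factor(truth)))) /
    length(got$label)
  tv <- sum(abs(comp_t - comp_p)) / 2
  expect_lte(tv, 0.05)
})

test_that("determinism: identical seeds reproduce the whole validation table", {
  tab <- simulate_marker_table(400, n_types = 3, n_markers = 12, seed = 5)
  a <- validate_propagation(tab, tab$label, proportions = c(0.3, 0.6),
                            n_panels = 4, seed = 11)
  b <- validate_propagation(tab, tab$label, proportions = c(0.3, 0.6),
                            n_panels = 4, seed = 11)
  expect_identical(a, b)
})
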