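test_that("silhouette matches brute-force evaluation on small fixtures", {
  set.seed(7)
  for (rep in 1:10) {
    pts <- matrix(rnorm(10), 5, 2)
    m <- as.matrix(dist(pts))
    labels <- sample(1:2, 5, replace = TRUE)
    if (length(unique(labels)) < 2) labels[1] <- 3 - labels[1]
    expect_equal(silhouette_width(m, labels), brute_silhouette(m, labels),
                 tolerance = 1e-12)
  }
})

test_that("silhouette agrees with the cluster package and handles singletons", {
  skip_if_not_installed("cluster")
  set.seed(12)
  pts <- matrix(rnorm(30), 15, 2)
  m <- as.matrix(dist(pts))
  labels <- c(rep(1, 7), rep(2, 7), 3)  # cluster 3 is a singleton
  ref <- mean(cluster::silhouette(labels, dmatrix = m)[, "sil_width"])
  expect_equal(silhouette_width(m, labels), ref, tolerance = 1e-12)
})

test_that("two separated point masses give silhouette 1", {
  m <- matrix(5, 6, 6); m[1:3, 1:3] <- 0; m[4:6, 4:6] <- 0
  expect_equal(silhouette_width(m, c(1, 1, 1, 2, 2, 2)), 1)
})

test_that("random labels on one blob give no substantial structure", {
  set.seed(3)
  pts <- matrix(rnorm(200), 100, 2)
  m <- as.matrix(dist(pts))
  labels <- sample(1:2, 100, replace = TRUE)
  expect_lte(silhouette_width(m, labels), 0.25)
})

test_that("CH in the PCoA embedding equals classic CH for Euclidean input", {
  set.seed(21)
  pts <- matrix(rnorm(40), 20, 2)
  m <- as.matrix(dist(pts))
  labels <- rep(1:2, each = 10)
  expect_equal(ch_index(m, labels), brute_ch(pts, labels), tolerance = 1e-6)
})

test_that("CH separates structure from noise and caps degenerate cases", {
  set.seed(9)
  blob <- rbind(matrix(rnorm(60, 0, 0.1), 30, 2),
                matrix(rnorm(60, 5, 0.1), 30, 2))
  m <- as.matrix(dist(blob))
  true_labels <- rep(1:2, each = 30)
  expect_gt(ch_index(m, true_labels), 100)
  expect_lt(ch_index(m, rep(1:2, 30)), 5)  # labels orthogonal to structure

  # identical points within clusters -> W = 0 -> capped sentinel
  m0 <- matrix(4, 4, 4); m0[1:2, 1:2] <- 0; m0[3:4, 3:4] <- 0
  expect_equal(ch_index(m0, c(1, 1, 2, 2)), 1e12)
  expect_error(ch_index(m, rep(1, 60)), "k = 1")
})

test_that("medoid CH variant also ranks true structure above noise", {
  set.seed(29)
  blob <- rbind(matrix(rnorm(40, 0, 0.2), 20, 2),
                matrix(rnorm(40, 4, 0.2), 20, 2))
  m <- as.matrix(dist(blob))
  expect_gt(ch_index(m, rep(1:2, each = 20), variant = "medoid"),
            ch_index(m, rep(1:2, 20), variant = "medoid"))
})

test_that("prediction strength is 1 for two point masses and bounded in general", {
  m <- matrix(5, 8, 8); m[1:4, 1:4] <- 0; m[5:8, 5:8] <- 0
  expect_equal(prediction_strength(m, 2, repeats = 5, seed = 1), 1)

  tab <- random_relative(30, 8, seed = 50)
  d <- jsd_distance(tab)
  for (k in 2:4) {
    ps <- prediction_strength(d, k, repeats = 5, seed = 2)
    expect_gte(ps, 0); expect_lte(ps, 1)
  }
  expect_error(prediction_strength(d, 20, repeats = 2, seed = 1), "half")
})

test_that("an unclustered Gaussian blob fails the strong-clustering bar at k=4", {
  set.seed(31)
  pts <- matrix(rnorm(200 * 2), 200, 2)
  m <- as.matrix(dist(pts))
  ps <- prediction_strength(m, 4, repeats = 20, seed = 8)
  expect_lt(ps, 0.9)
})

test_that("prediction strength is reproducible given a seed", {
  tab <- random_relative(24, 6, seed = 60)
  d <- jsd_distance(tab)
  expect_identical(prediction_strength(d, 2, repeats = 10, seed = 4),
                   prediction_strength(d, 2, repeats = 10, seed = 4))
})

test_that("validation thresholds classify as reported for male-stratum-like output", {
  # PS 0.96 / SI 0.34 -> strong clustering, weak structure, reliable
  expect_identical(enterotyper:::classify_ps(0.96), "strong clustering")
  expect_identical(enterotyper:::classify_si(0.34), "weak structure")
  expect_true(0.96 >= 0.9 && 0.34 > 0.25)
  # band edges
  expect_identical(enterotyper:::classify_ps(0.89), "no strong clustering")
  expect_identical(enterotyper:::classify_si(0.25), "no substantial structure")
  expect_identical(enterotyper:::classify_si(0.51), "reasonable structure")
  expect_identical(enterotyper:::classify_si(0.76), "strong structure")
})

test_that("enterotype fit recovers two strong archetypes as reliable k = 2", {
  coh <- two_archetype_cohort(n = 120, concentration = 200, seed = 84)
  fit <- enterotype(coh$counts, k_range = 2:6, ps_repeats = 10, seed = 5)
  expect_equal(fit$best_k, 2L)
  expect_true(fit$reliable)
  expect_identical(fit$ps_class, "strong clustering")
  expect_gt(adjusted_rand(fit$partition$clustering, coh$true_labels), 0.95)
  expect_equal(unname(fit$ch_by_k[as.character(fit$best_k)]), max(fit$ch_by_k))
})

test_that("a single archetype is not validated as reliable clustering", {
  coh <- single_archetype_cohort(n = 120, seed = 85)
  fit <- enterotype(coh$counts, k_range = 2:5, ps_repeats = 10, seed = 6)
  expect_false(fit$reliable)
  expect_lte(fit$si, 0.25)
})

test_that("forcing k overrides CH selection and predict assigns new samples", {
  coh <- two_archetype_cohort(n = 80, seed = 86)
  fit <- enterotype(coh$counts, k_range = 2:4, force_k = 3, ps_repeats = 5, seed = 2)
  expect_equal(fit$best_k, 3L)

  fit2 <- enterotype(coh$counts, k_range = 2:4, ps_repeats = 5, seed = 2)
  newc <- two_archetype_cohort(n = 30, seed = 87)
  pred <- predict(fit2, newc$counts)
  expect_length(pred, 30)
  # predicted clusters align with the generator's labels
  expect_gt(adjusted_rand(pred, newc$true_labels), 0.95)
})
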