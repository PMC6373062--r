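two_blob_data <- function(n = 60, d = 5, sd = 0.1, seed = 14) {
  withr::with_seed(seed, rbind(
    matrix(rnorm(2 * n, 0, sd), n, 2),
    matrix(rnorm(2 * n, d, sd), n, 2)
  ))
}

test_that("fuzzy C-means recovers well-separated cloud centers", {
  X <- two_blob_data()
  m <- fcm_fit(X, c = 2, q = 2, seed = 3)
  ctrs <- m$centers[order(m$centers[, 1]), ]
  expect_lt(max(abs(ctrs[1, ] - c(0, 0))), 0.1)
  expect_lt(max(abs(ctrs[2, ] - c(5, 5))), 0.1)
  expect_true(all(diff(m$objective_trace) <= 1e-8))
})

test_that("memberships normalise, and limits behave (equidistant point, center hit)", {
  X <- two_blob_data()
  m <- fcm_fit(X, c = 2, q = 2, seed = 3)
  mid <- colMeans(m$centers)
  u <- membership(mid, m)
  expect_equal(unname(u), c(0.5, 0.5), tolerance = 1e-6)
  at_center <- membership(m$centers[1, ], m)
  expect_equal(unname(at_center), c(1, 0))
  set.seed(5)
  U <- membership(matrix(rnorm(40), 20, 2), m)
  expect_lt(max(abs(colSums(U) - 1)), 1e-9)
})

test_that("memberships match a direct evaluation of the ratio formula", {
  # independent oracle: literal 1 / sum_j (d_ik/d_jk)^(2/(q-1))
  set.seed(21)
  centers <- matrix(rnorm(6), 3, 2)
  X <- matrix(rnorm(20), 10, 2)
  q <- 1.7
  m <- structure(list(centers = centers, q = q, dim = 2), class = "fcm_model")
  U <- membership(X, m)
  for (k in 1:10) {
    d <- sqrt(colSums((t(centers) - X[k, ])^2))
    for (i in 1:3) {
      want <- 1 / sum((d[i] / d)^(2 / (q - 1)))
      expect_equal(U[i, k], want, tolerance = 1e-10)
    }
  }
})

test_that("the fuzzifier's hard limit concentrates memberships on separated data", {
  X <- two_blob_data()
  m <- fcm_fit(X, c = 2, q = 1.01, seed = 3)
  U <- membership(X, m)
  expect_gte(min(apply(U, 2, max)), 0.999)
})

test_that("fits are deterministic under a seed and guard their contracts", {
  X <- two_blob_data()
  a <- fcm_fit(X, c = 3, q = 1.5, seed = 9, restarts = 2)
  b <- fcm_fit(X, c = 3, q = 1.5, seed = 9, restarts = 2)
  expect_identical(a$centers, b$centers)
  expect_error(fcm_fit(X[1:3, ], c = 5), "more points")
  expect_error(fcm_fit(X, c = 1), "at least 2")
  expect_error(fcm_fit(X, c = 2, q = 1), "exceed 1")
  Xbad <- X; Xbad[1, 1] <- NA
  expect_error(fcm_fit(Xbad, c = 2), "non-finite")
  expect_error(membership(c(1, 2, 3), a), "dimension")
})

test_that("centers agree with an independent FCM implementation on easy data", {
  skip_if_not_installed("e1071")
  X <- two_blob_data(n = 40)
  ours <- fcm_fit(X, c = 2, q = 2, seed = 2)
  ref <- e1071::cmeans(X, centers = 2, m = 2)
  ours_sorted <- ours$centers[order(ours$centers[, 1]), ]
  ref_sorted <- ref$centers[order(ref$centers[, 1]), ]
  expect_lt(max(abs(ours_sorted - ref_sorted)), 0.05)
})

test_that("defuzzification reproduces a hand-computed Bayes table on the 3-cluster toy", {
  # class A: (10, 0, 5) points per cluster; class B: (0, 10, 5); alpha = 0
  u <- matrix(0, 3, 30)
  assign <- c(rep(1, 10), rep(3, 5), rep(2, 10), rep(3, 5))
  for (k in 1:30) u[assign[k], k] <- 1
  model <- structure(list(u = u, c = 3L), class = "fcm_model")
  labels <- factor(c(rep("A", 15), rep("B", 15)))
  dz <- defuzz_fit(model, labels, alpha = 0)
  expect_equal(unname(dz$likelihood["A", ]), c(10, 0, 5) / 15)
  expect_equal(unname(dz$likelihood["B", ]), c(0, 10, 5) / 15)
  expect_equal(unname(dz$priors), c(0.5, 0.5))
  expect_equal(unname(dz$posterior[, 1]), c(1, 0))
  expect_equal(unname(dz$posterior[, 2]), c(0, 1))
  expect_equal(unname(dz$posterior[, 3]), c(0.5, 0.5))
  expect_lt(max(abs(colSums(dz$posterior) - 1)), 1e-9)
})

test_that("pure clusters give one-hot posteriors and uniform mixes return the priors", {
  u <- matrix(0, 2, 20)
  u[1, 1:10] <- 1; u[2, 11:20] <- 1
  model <- structure(list(u = u, c = 2L), class = "fcm_model")
  pure <- defuzz_fit(model, factor(c(rep("A", 10), rep("B", 10))), alpha = 0)
  expect_equal(unname(pure$posterior), matrix(c(1, 0, 0, 1), 2))
  # every cluster contains the same class mix: posterior = priors
  mixed_labels <- factor(rep(c("A", "A", "A", "B"), 5))
  u2 <- matrix(0, 2, 20)
  u2[1, c(1:3, 4)] <- 1  # cluster 1: 3 A + 1 B
  u2[1, 5:8] <- 1        # cluster 1: 6 A + 2 B total
  u2[2, 9:20] <- 1       # cluster 2: 9 A + 3 B
  mix <- defuzz_fit(structure(list(u = u2, c = 2L), class = "fcm_model"),
                    mixed_labels, alpha = 0)
  expect_equal(unname(mix$posterior[, 1]), c(0.75, 0.25))
  expect_equal(unname(mix$posterior[, 2]), c(0.75, 0.25))
  expect_error(defuzz_fit(model, factor(rep("A", 20), levels = c("A", "B"))),
               "zero training points")
})

test_that("the full classifier separates generated class tables", {
  # widely separated variant of the class statistics
  sep_stats <- dplyr::mutate(class_stats(), sd = sd / 3)
  tbl <- gen_feature_table(40, seed = 31, stats = sep_stats)
  test_tbl <- gen_feature_table(25, seed = 32, stats = sep_stats)
  clf <- fit_cell_classifier(tbl, features = stats_features, c = 25,
                             seed = 4, restarts = 2)
  pred <- predict(clf, test_tbl)
  expect_lt(max(abs(rowSums(as.matrix(pred[paste0("post_", cell_classes)])) - 1)), 1e-9)
  expect_gte(mean(pred$binary == binary_label(as.character(test_tbl$label))), 0.95)
  # under the shipped (overlapping) statistics the binary call still
  # separates the bulk of the classes
  tbl2 <- gen_feature_table(40, seed = 31)
  te2 <- gen_feature_table(25, seed = 32)
  clf2 <- fit_cell_classifier(tbl2, features = stats_features, c = 25,
                              seed = 4, restarts = 2)
  pred2 <- predict(clf2, te2)
  expect_gte(mean(pred2$binary == binary_label(as.character(te2$label))), 0.85)
})

test_that("a point at a pure-class cluster center gets a confident posterior", {
  X <- two_blob_data(n = 40)
  m <- fcm_fit(X, c = 2, q = 1.5, seed = 6)
  labels <- factor(binary_label(rep(c("INTERMEDIATE", "SEVERE"), each = 40)))
  dz <- defuzz_fit(m, labels, alpha = 0)
  pred <- fcm_predict(matrix(m$centers[1, ], 1), m, dz)
  expect_gte(max(pred[paste0("post_", dz$classes)]), 0.99)
})

test_that("cluster-count selection reports the error curve and its argmin", {
  tbl <- gen_feature_table(12, seed = 8) |>
    dplyr::filter(label %in% c("SUPERFICIAL", "COLUMNAR", "CARCINOMA_IN_SITU"))
  tbl$label <- droplevels(tbl$label)
  rep1 <- choose_cluster_count(tbl, c(2, 3, 5), features = c("nucleus_area", "nc_ratio"),
                               k = 3, seed = 2)
  expect_equal(nrow(rep1), 3)
  chosen <- attr(rep1, "chosen")
  expect_equal(chosen, rep1$clusters[which.min(rep1$cv_error)])
  rep2 <- choose_cluster_count(tbl, c(2, 3, 5), features = c("nucleus_area", "nc_ratio"),
                               k = 3, seed = 2)
  expect_identical(as.data.frame(rep1), as.data.frame(rep2))
  single <- choose_cluster_count(tbl, 4, features = c("nucleus_area", "nc_ratio"),
                                 k = 3, seed = 2)
  expect_equal(attr(single, "chosen"), 4L)
})

test_that("slide screening applies the abnormal-count threshold", {
  cells <- tibble::tibble(binary = factor(rep("NORMAL", 100),
                                          levels = c("NORMAL", "ABNORMAL")))
  expect_equal(screen_slide(cells)$diagnosis, "NEGATIVE")
  cells$binary[5] <- "ABNORMAL"
  expect_equal(screen_slide(cells)$diagnosis, "POSITIVE")
  cells$binary[6] <- "ABNORMAL"
  expect_equal(screen_slide(cells, min_abnormal = 3)$diagnosis, "NEGATIVE")
})
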