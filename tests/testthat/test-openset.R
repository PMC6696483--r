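# small but non-trivial training/test pools shared across tests
osd_train <- generate_dataset(8, 10, 400, seed = 42)
osd_test <- generate_dataset(8, 10, 400, seed = 42, later = TRUE)

test_that("the ensemble holds one trained machine per class with zero training error", {
  ens <- train_ensemble(osd_train, J = 15, n_folds = 2, n_starts = 5, seed = 1)
  expect_length(ens$models, 8)
  expect_equal(ens$unknown_class_id, 9L)
  for (i in seq_along(ens$models)) {
    m <- ens$models[[i]]
    y <- ifelse(osd_train$labels == ens$class_ids[i], 1, -1)
    f <- decision_value(m, ens$train_scores)
    expect_equal(mcr(sign(f), y), 0)
    # dual box constraints and equality constraint on the stored machine
    expect_true(all(m$lambda > 0 & m$lambda <= m$kernel$C + 1e-12))
    expect_lt(abs(sum(m$dual_coeffs)), 1e-6)
  }
})

test_that("a two-class ensemble gives sign-opposed decisions on training samples", {
  d2 <- subset_samples(osd_train, osd_train$labels <= 2)
  ens <- train_ensemble(d2, J = 5, n_folds = 2, n_starts = 5, seed = 2)
  f1 <- decision_value(ens$models[[1]], ens$train_scores)
  f2 <- decision_value(ens$models[[2]], ens$train_scores)
  expect_true(all(sign(f1) == -sign(f2)))
})

test_that("training refuses classes smaller than the CV fold count", {
  d <- subset_samples(osd_train, c(which(osd_train$labels == 1),
                                   which(osd_train$labels == 2)[1]))
  expect_error(train_ensemble(d, J = 3, n_folds = 2), "class 2")
  expect_error(train_ensemble(osd_train, J = 15, knn_k = 2), "odd")
})

test_that("known, outer and far-away samples get the right open-set labels", {
  train <- subset_samples(osd_train, osd_train$labels != 8)
  ens <- train_ensemble(train, J = 15, n_folds = 2, n_starts = 5, seed = 3)

  # drifted known samples: classified to their own class
  known <- subset_samples(osd_test, osd_test$labels %in% 1:7)
  pred_known <- classify_samples(ens, known)
  expect_gt(mean(pred_known == known$labels), 0.95)

  # the withheld compound: rejected into the extra class
  outer <- subset_samples(osd_test, osd_test$labels == 8)
  pred_outer <- classify_samples(ens, outer)
  expect_gt(mean(pred_outer == ens$unknown_class_id), 0.95)

  # every assignment is a single label from {classes, C+1}
  expect_true(all(c(pred_known, pred_outer) %in%
                    c(ens$class_ids, ens$unknown_class_id)))

  # a sample pushed far from all training data in PC space is rejected:
  # all GRBF responses decay to the (negative) biases
  expect_true(all(vapply(ens$models, function(m) m$bias, numeric(1)) < 0))
  z_far <- ens$train_scores[1, ] + 1e3
  far_spec <- pca_reconstruct(ens$pca, z_far)
  expect_equal(as.integer(classify_sample(ens, drop(far_spec))),
               ens$unknown_class_id)

  expect_error(classify_samples(ens, matrix(0, 1, 7)), "columns")
})

test_that("multiply-claimed samples are adjudicated by the kNN vote with distance tie-break", {
  # hand-built two-dimensional configuration: three machines all claim z0
  mkmodel <- function(center, cl) {
    structure(list(support_vectors = matrix(center, 1, 2),
                   dual_coeffs = 1, lambda = 1, bias = -0.1,
                   kernel = kernel_params("grbf", sigma2 = 50, C = 1),
                   positive_class = cl, n_train = 9L),
              class = "binary_svm")
  }
  pca <- structure(list(mean_spectrum = c(0, 0), loadings = diag(2),
                        eigenvalues = c(1, 1), explained_ratio = c(0.5, 0.5),
                        n_train = 9L, total_variance = 2),
                   class = "pca_model")
  train_scores <- rbind(matrix(c(0.4, 0, 0.5, 0.1, 0.45, -0.1), 3, 2, byrow = TRUE),
                        matrix(c(-2, 0, -2.1, 0.1, -2, -0.2), 3, 2, byrow = TRUE),
                        matrix(c(0, 2, 0.1, 2.1, -0.1, 2), 3, 2, byrow = TRUE))
  ens <- structure(list(models = list(mkmodel(c(1, 0), 1L),
                                      mkmodel(c(-1, 0), 2L),
                                      mkmodel(c(0, 1), 3L)),
                        pca = pca, class_ids = 1:3, unknown_class_id = 4L,
                        knn_k = 3L, train_scores = train_scores,
                        train_labels = rep(1:3, each = 3)),
                   class = "openset_ensemble")
  # z0 near class 1's training cluster: 3 of 3 nearest neighbours in class 1
  res <- classify_sample(ens, c(0.45, 0))
  expect_equal(as.integer(res), 1L)
  expect_equal(attr(res, "n_claims"), 3L)

  # k = 1 with three claimants: vote decided by the single nearest neighbour
  ens$knn_k <- 1L
  expect_equal(as.integer(classify_sample(ens, c(-1.8, 0))), 2L)
})

test_that("the protocol enumerates holdouts x fractions and scores cells correctly", {
  pr <- run_protocol(osd_train, osd_test, n_test = 10, seed = 9,
                     J = 15, n_folds = 2, n_starts = 5)
  expect_equal(nrow(pr$cells), 8 * 11)
  expect_equal(length(unique(pr$cells$holdout)), 8)
  expect_equal(length(unique(pr$cells$outer_fraction)), 11)
  expect_true(all(pr$cells$accuracy >= 0 & pr$cells$accuracy <= 100))
  expect_true(all(pr$cells$n_correct <= pr$cells$n_test))
  expect_equal(pr$grand_mean_accuracy, mean(pr$cells$accuracy))

  # fraction-0 cells contain no outer-class samples by construction;
  # fraction-1 accuracy is exactly the rate of unknown-class assignment
  f1 <- pr$cells[pr$cells$outer_fraction == 1, ]
  expect_equal(f1$accuracy, 100 * f1$n_unknown_assigned / f1$n_test)
})
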