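# Shared tiny planted-signal dataset for the model tests (built once; the
# SGD fits below are the slow part).
model_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      w <- tiny_world(n = 60, signal_strength = 1, seed = 301)
      cache <<- build_dataset(w$planted$peaks, w$planted$sequences,
                              w$sim$genome, seed = 302)
    }
    cache
  }
})

test_that("single member learns a separable toy problem", {
  X <- Matrix::sparseMatrix(i = 1:40, j = rep(1, 40),
                            x = c(rep(1, 20), rep(0, 20)), dims = c(40, 1))
  y <- c(rep(1, 20), rep(0, 20))
  fit <- train_member(X, y, seed = 1)
  expect_gt(fit$weights[1], 0)
  pred <- as.numeric(stats::plogis(as.matrix(X) %*% fit$weights +
                                     fit$intercept))
  expect_equal(as.numeric(pred > 0.5), y)
  expect_error(train_member(X, rep(1, 40)), "single class")
})

test_that("strong regularization shrinks weights toward zero", {
  set.seed(11)
  X <- Matrix::Matrix(matrix(rpois(200, 2), 20, 10), sparse = TRUE)
  y <- rep(c(0, 1), 10)
  small <- train_member(X, y, l2_alpha = 0.01, seed = 2)
  huge <- train_member(X, y, l2_alpha = 1e6, seed = 2)
  expect_lt(sqrt(sum(huge$weights^2)), 1e-3)
  expect_gt(sqrt(sum(small$weights^2)), sqrt(sum(huge$weights^2)))
})

test_that("training is deterministic given the seed", {
  set.seed(12)
  X <- Matrix::Matrix(matrix(rpois(300, 1), 30, 10), sparse = TRUE)
  y <- rep(c(0, 1), 15)
  f1 <- train_member(X, y, seed = 77)
  f2 <- train_member(X, y, seed = 77)
  f3 <- train_member(X, y, seed = 78)
  expect_identical(f1$weights, f2$weights)
  expect_false(identical(f1$weights, f3$weights))
})

test_that("ensemble prediction is the mean of member probabilities", {
  ds <- model_fixture()
  m1 <- fit_kmer_ensemble(ds$sequence, ds$label, n_members = 1, seed = 5)
  m2 <- fit_kmer_ensemble(ds$sequence, ds$label, n_members = 2, seed = 5)
  test_seqs <- ds$sequence[seq(1, nrow(ds), by = 7)]
  # n_members = 1: ensemble equals its single member
  X <- count_features(test_seqs, m1$vocabulary)
  single <- as.numeric(stats::plogis(as.matrix(X %*% m1$W) +
                                       m1$intercepts[1]))
  expect_equal(predict_probability(m1, test_seqs), single)
  # manual member averaging for n_members = 2
  X2 <- count_features(test_seqs, m2$vocabulary)
  probs <- stats::plogis(sweep(as.matrix(X2 %*% m2$W), 2,
                               m2$intercepts, `+`))
  expect_equal(predict_probability(m2, test_seqs), rowMeans(probs))
  p <- predict_probability(m2, ds$sequence)
  expect_true(all(p >= 0 & p <= 1))
  # a sequence with no vocabulary overlap scores mean(plogis(intercepts))
  novocab <- paste(rep("N", 501), collapse = "")
  expect_equal(predict_probability(m2, novocab),
               mean(stats::plogis(m2$intercepts)))
})

test_that("roc_auc matches the pairwise oracle and handles edge cases", {
  expect_equal(roc_auc(c(1, 0), c(0.9, 0.1)), 1.0)
  expect_equal(roc_auc(c(1, 0, 1, 0), rep(0.5, 4)), 0.5)
  expect_error(roc_auc(c(1, 1), c(0.1, 0.2)), "both classes")
  set.seed(13)
  for (i in 1:5) {
    n <- sample(20:200, 1)
    labels <- rbinom(n, 1, 0.4)
    if (length(unique(labels)) < 2) labels[1:2] <- c(0, 1)
    scores <- round(runif(n), 2)  # rounding forces ties
    expect_equal(roc_auc(labels, scores), oracle_auc(labels, scores))
  }
  # second independent route: pROC on one instance
  set.seed(14)
  labels <- rbinom(80, 1, 0.5); labels[1:2] <- 0:1
  scores <- runif(80)
  expect_equal(roc_auc(labels, scores),
               as.numeric(pROC::auc(pROC::roc(labels, scores,
                                              quiet = TRUE,
                                              direction = "<"))))
})

test_that("model serialization round-trips predictions exactly", {
  ds <- model_fixture()
  m <- fit_kmer_ensemble(ds$sequence, ds$label, n_members = 2, seed = 6)
  path <- withr::local_tempfile(fileext = ".json")
  write_model(m, path)
  m2 <- read_model(path)
  test_seqs <- ds$sequence[1:10]
  expect_equal(predict_probability(m2, test_seqs),
               predict_probability(m, test_seqs))
  expect_equal(m2$width, m$width)
})

test_that("cross-validation has no leakage and separates planted signal", {
  ds <- model_fixture()
  cv <- cross_validate(ds, n_members = 4, seed = 7)
  expect_equal(sort(names(cv$fold_auc)), sort(unique(ds$chrom)))
  expect_equal(nrow(cv$predictions), nrow(ds))
  expect_equal(anyDuplicated(cv$predictions$id), 0L)
  # out-of-fold predictions are made on the sequence's own arm only
  expect_equal(cv$predictions$fold, cv$predictions$chrom)
  # planted signal at strength 1 is learnable across arms
  expect_gt(cv$pooled_auc, 0.9)
  # pooled AUC is the AUC of the concatenated out-of-fold predictions
  expect_equal(cv$pooled_auc,
               roc_auc(cv$predictions$label, cv$predictions$probability))
})

test_that("deleting a test sequence never changes a fold's model", {
  ds <- model_fixture()
  # drop one 2L (test-fold) sequence; the 2L fold's training set is
  # untouched, so its out-of-fold predictions must be identical
  drop_id <- which(ds$chrom == "2L")[1]
  cv_full <- cross_validate(ds, n_members = 2, seed = 8)
  cv_drop <- cross_validate(ds[-drop_id, ], n_members = 2, seed = 8)
  kept <- intersect(cv_full$predictions$id[cv_full$predictions$chrom == "2L"],
                    cv_drop$predictions$id)
  p_full <- cv_full$predictions[match(kept, cv_full$predictions$id), ]
  p_drop <- cv_drop$predictions[match(kept, cv_drop$predictions$id), ]
  expect_equal(p_full$probability, p_drop$probability)
})

test_that("label permutation drives CV AUC to chance", {
  ds <- model_fixture()
  null_ds <- ds
  null_ds$label <- with_seed(909, sample(ds$label))
  cv <- cross_validate(null_ds, n_members = 4, seed = 10)
  expect_gt(cv$pooled_auc, 0.35)
  expect_lt(cv$pooled_auc, 0.65)
})
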