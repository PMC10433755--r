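default_hyperparams <- function() {
  list(k_min = 6L, k_max = 8L, n_members = 48L, l2_alpha = 0.01,
       max_epochs = 1000L, tol = 1e-3, n_no_change = 5L, eta0 = 0.02)
}

#' Train one L2-regularized logistic regression by SGD
#'
#' Minimizes mean logistic loss plus `l2_alpha/2 * ||w||^2` (intercept
#' unpenalized) by stochastic gradient descent with per-epoch example
#' shuffling; the inverse-scaling learning rate and stall-based early stop
#' are described in the package vignette. Deterministic given the seed.
#'
#' @param X sparse or dense numeric matrix, rows = samples.
#' @param y 0/1 labels.
#' @param l2_alpha L2 penalty strength (default 0.01).
#' @param max_epochs maximum passes over the data (default 1000).
#' @param tol early-stop tolerance on the mean epoch loss.
#' @param n_no_change epochs without improvement before stopping.
#' @param eta0 initial learning rate.
#' @param seed integer seed driving the shuffling.
#' @return list with `weights`, `intercept`, `epochs`, `final_loss`.
#' @export
train_member <- function(X, y, l2_alpha = 0.01, max_epochs = 1000L,
                         tol = 1e-3, n_no_change = 5L, eta0 = 0.02,
                         seed = 1L) {
  y <- as.numeric(y)
  if (length(unique(y)) < 2) stop("training labels contain a single class")
  if (nrow(X) != length(y)) stop("X rows must match length(y)")
  Xt <- methods::as(Matrix::t(methods::as(X, "CsparseMatrix")), "CsparseMatrix")
  sgd_logreg_fit(Xt, y, l2_alpha, as.integer(max_epochs), tol,
                 as.integer(n_no_change), eta0, as.integer(seed))
}

train_members_on <- function(Xt, y, hp, base_seed) {
  seeds <- derive_seed(base_seed, seq_len(hp$n_members))
  fits <- lapply(seeds, function(s) {
    sgd_logreg_fit(Xt, y, hp$l2_alpha, as.integer(hp$max_epochs), hp$tol,
                   as.integer(hp$n_no_change), hp$eta0, as.integer(s))
  })
  list(W = vapply(fits, `[[`, numeric(nrow(Xt)), "weights"),
       intercepts = vapply(fits, `[[`, numeric(1), "intercept"),
       epochs = vapply(fits, `[[`, numeric(1), "epochs"),
       seeds = seeds)
}

#' Fit a k-mer ensemble enhancer model
#'
#' The sequence classifier: builds the 6-8-mer vocabulary from the training
#' sequences, featurizes them as overlapping counts, and trains an ensemble
#' of `n_members` (default 48) L2-regularized logistic regressions by SGD.
#' Every member sees the full training set -- no bootstrap resampling of
#' rows or features -- and members differ only through the random order in
#' which SGD visits examples, each member seeded from `derive_seed(seed,
#' member_index)`. The ensemble probability is the arithmetic mean of the
#' member probabilities.
#'
#' @param sequences training sequences (character or `DNAStringSet`).
#' @param labels 0/1 labels (1 = peak, 0 = control).
#' @param k_min,k_max k-mer range (defaults 6 and 8).
#' @param n_members ensemble size (default 48).
#' @param l2_alpha,max_epochs,tol,n_no_change,eta0 SGD settings, see
#'   [train_member()].
#' @param seed base integer seed.
#' @param width training window width stored for compatibility checks when
#'   the model is applied to new peak sets (default inferred from the
#'   first sequence).
#' @return object of class `kmer_ensemble`.
#' @export
fit_kmer_ensemble <- function(sequences, labels, k_min = 6, k_max = 8,
                              n_members = 48, l2_alpha = 0.01,
                              max_epochs = 1000L, tol = 1e-3,
                              n_no_change = 5L, eta0 = 0.02, seed = 1L,
                              width = NULL) {
  labels <- as.integer(labels)
  if (length(sequences) != length(labels)) {
    stop("sequences and labels differ in length")
  }
  hp <- list(k_min = as.integer(k_min), k_max = as.integer(k_max),
             n_members = as.integer(n_members), l2_alpha = l2_alpha,
             max_epochs = as.integer(max_epochs), tol = tol,
             n_no_change = as.integer(n_no_change), eta0 = eta0)
  # count once; the vocabulary is the observed-column subset
  X_full <- kmer_count_matrix(sequences, k_min, k_max)
  seen <- colnames(X_full)[Matrix::colSums(X_full) > 0]
  vocab <- structure(list(kmers = sort(seen, method = "radix"),
                          k_min = as.integer(k_min),
                          k_max = as.integer(k_max)),
                     class = "kmer_vocabulary")
  X <- X_full[, match(vocab$kmers, colnames(X_full)), drop = FALSE]
  Xt <- methods::as(Matrix::t(X), "CsparseMatrix")
  if (length(unique(labels)) < 2) stop("training labels contain a single class")
  fit <- train_members_on(Xt, as.numeric(labels), hp, seed)
  structure(list(vocabulary = vocab, W = fit$W, intercepts = fit$intercepts,
                 hyperparams = hp, seed = as.integer(seed),
                 member_seeds = fit$seeds, epochs = fit$epochs,
                 width = as.integer(width %||% nchar(sequences[[1]]))),
            class = "kmer_ensemble")
}

#' @export
print.kmer_ensemble <- function(x, ...) {
  cat("k-mer ensemble:", ncol(x$W), "members,",
      length(x$vocabulary$kmers), "features (k =",
      x$hyperparams$k_min, "-", x$hyperparams$k_max, "), window",
      x$width, "bp\n")
  invisible(x)
}

#' Predict peak probabilities for sequences
#'
#' Mean over ensemble members of `plogis(w'x + b)`, where `x` is the
#' sequence's count vector over the model's vocabulary.
#'
#' @param model a [fit_kmer_ensemble()] model.
#' @param sequences character or `DNAStringSet`.
#' @return numeric vector of probabilities in \[0, 1\].
#' @export
predict_probability <- function(model, sequences) {
  stopifnot(inherits(model, "kmer_ensemble"))
  X <- count_features(sequences, model$vocabulary)
  margins <- as.matrix(X %*% model$W)
  margins <- sweep(margins, 2, model$intercepts, `+`)
  rowMeans(stats::plogis(margins))
}

#' @rdname predict_probability
#' @param object a `kmer_ensemble`.
#' @param newdata sequences to score.
#' @param ... ignored.
#' @export
predict.kmer_ensemble <- function(object, newdata, ...) {
  predict_probability(object, newdata)
}

#' ROC area under the curve
#'
#' Rank-statistic (Mann-Whitney) form: the probability that a random
#' positive scores above a random negative, with ties counted half.
#'
#' @param labels 0/1 labels.
#' @param scores numeric scores.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(labels, scores) {
  labels <- as.integer(labels)
  if (length(labels) != length(scores)) stop("length mismatch")
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores)  # average ranks on ties
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Chromosome-arm cross-validation of the k-mer ensemble
#'
#' For each fold (chromosome arm), the vocabulary and all ensemble members
#' are fit on the sequences of the other arms and probabilities are
#' predicted for the held-out arm, so test-only k-mers are never part of
#' the feature space. Reports per-fold AUCs and the pooled AUC over the
#' concatenated out-of-fold predictions (the headline number; pooling is
#' the only aggregation that yields a single ROC).
#'
#' @param dataset tibble from [build_dataset()] (`sequence`, `label`,
#'   `chrom` columns).
#' @param k_min,k_max,n_members,l2_alpha,max_epochs,tol,n_no_change,eta0
#'   model settings, see [fit_kmer_ensemble()].
#' @param seed base seed; each fold trains from `derive_seed(seed, fold)`.
#' @param arms fold labels (default the five large arms).
#' @return object of class `cv_result`: `fold_auc` (named numeric),
#'   `pooled_auc`, and `predictions` (tibble with out-of-fold
#'   probabilities, one row per sequence).
#' @export
cross_validate <- function(dataset, k_min = 6, k_max = 8, n_members = 48,
                           l2_alpha = 0.01, max_epochs = 1000L, tol = 1e-3,
                           n_no_change = 5L, eta0 = 0.02, seed = 1L,
                           arms = FLY_ARMS) {
  fold <- partition_folds(dataset, arms)
  used <- levels(droplevels(fold))
  hp <- list(k_min = as.integer(k_min), k_max = as.integer(k_max),
             n_members = as.integer(n_members), l2_alpha = l2_alpha,
             max_epochs = as.integer(max_epochs), tol = tol,
             n_no_change = as.integer(n_no_change), eta0 = eta0)
  # Count once for the whole dataset; per-fold vocabularies are column
  # subsets (a sequence's counts do not depend on the fold split), so
  # test-only k-mers still never enter a fold's feature space.
  X <- kmer_count_matrix(dataset$sequence, k_min, k_max)
  preds <- vector("list", length(used))
  fold_auc <- stats::setNames(numeric(length(used)), used)
  for (fi in seq_along(used)) {
    f <- used[fi]
    test <- which(fold == f)
    train <- which(fold != f)
    if (length(unique(dataset$label[train])) < 2 ||
        length(unique(dataset$label[test])) < 2) {
      stop("fold ", f, " lacks one of the classes")
    }
    in_train <- Matrix::colSums(X[train, , drop = FALSE]) > 0
    cols <- match(sort(colnames(X)[in_train], method = "radix"),
                  colnames(X))
    Xtr <- X[train, cols, drop = FALSE]
    Xte <- X[test, cols, drop = FALSE]
    fit <- train_members_on(methods::as(Matrix::t(Xtr), "CsparseMatrix"),
                            as.numeric(dataset$label[train]), hp,
                            derive_seed(seed, fi))
    margins <- sweep(as.matrix(Xte %*% fit$W), 2, fit$intercepts, `+`)
    p <- rowMeans(stats::plogis(margins))
    fold_auc[f] <- roc_auc(dataset$label[test], p)
    preds[[fi]] <- tibble::tibble(id = dataset$id[test],
                                  chrom = dataset$chrom[test],
                                  fold = f,
                                  label = dataset$label[test],
                                  probability = p)
  }
  predictions <- do.call(rbind, preds)
  structure(list(fold_auc = fold_auc,
                 pooled_auc = roc_auc(predictions$label,
                                      predictions$probability),
                 predictions = predictions),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat("chromosome-fold CV: pooled AUC", sprintf("%.3f", x$pooled_auc), "\n")
  print(round(x$fold_auc, 3))
  invisible(x)
}

#' Serialize / restore a k-mer ensemble model
#'
#' JSON bundle holding the vocabulary, the member weight matrix and
#' intercepts, hyperparameters and seeds (schema version 1).
#'
#' @param model a `kmer_ensemble`.
#' @param path output `.json` path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "kmer_ensemble"))
  payload <- list(schema = "cresignal-kmer-ensemble/1",
                  k_min = model$hyperparams$k_min,
                  k_max = model$hyperparams$k_max,
                  hyperparams = model$hyperparams,
                  seed = model$seed, member_seeds = model$member_seeds,
                  width = model$width,
                  vocabulary = model$vocabulary$kmers,
                  intercepts = model$intercepts,
                  weights = t(model$W))
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(p$schema, "cresignal-kmer-ensemble/1")) {
    stop("unrecognized model schema")
  }
  vocab <- structure(list(kmers = p$vocabulary,
                          k_min = as.integer(p$k_min),
                          k_max = as.integer(p$k_max)),
                     class = "kmer_vocabulary")
  structure(list(vocabulary = vocab, W = t(p$weights),
                 intercepts = p$intercepts,
                 hyperparams = p$hyperparams, seed = p$seed,
                 member_seeds = p$member_seeds, epochs = NULL,
                 width = as.integer(p$width)),
            class = "kmer_ensemble")
}
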