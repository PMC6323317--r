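#' @title Stacked-generalization machinery
#' @description Out-of-fold (OOF) scoring is the backbone of the
#'   three-stage model: training data are split into k disjoint,
#'   label-stratified folds; each base model is fitted k times, each time
#'   holding one fold out, and a training row's meta-feature always comes
#'   from the model whose training folds excluded that row. For new data
#'   the k fold models predict and their scores are averaged.
#' @name stacker
NULL

#' Label-stratified fold assignment
#'
#' Each class's rows are shuffled and dealt cyclically over the k folds, so
#' fold class proportions match the data as closely as integer counts
#' allow. Classes with fewer than k rows are simply spread over distinct
#' folds (the stratification fallback); a class with a single row cannot be
#' scored out of fold and is an error.
#'
#' @param y Factor (or vector) of labels.
#' @param k Number of folds (>= 2).
#' @param seed Integer seed.
#' @return Integer vector of fold ids (1..k) aligned with `y`.
#' @export
stratified_folds <- function(y, k = 10L, seed = 1L) {
  k <- as.integer(k)
  if (k < 2L) stop("k must be >= 2", call. = FALSE)
  y <- as.character(y)
  tab <- table(y)
  if (any(tab < 2L)) {
    stop("stratification error: class '", names(tab)[which(tab < 2L)[1]],
         "' has fewer than 2 rows; merge rare classes or drop them before ",
         "stacking", call. = FALSE)
  }
  set.seed(seed)
  folds <- integer(length(y))
  offset <- 0L
  for (cls in names(tab)) {
    idx <- which(y == cls)
    idx <- idx[sample.int(length(idx))]
    folds[idx] <- ((offset + seq_along(idx) - 1L) %% k) + 1L
    offset <- offset + length(idx)
  }
  folds
}

#' Out-of-fold class scores
#'
#' @param X Numeric feature matrix.
#' @param y Factor response.
#' @param spec A [make_learner()] specification.
#' @param k Fold count (default 10).
#' @param seed Seed controlling the fold split.
#' @return List: `oof` (matrix, one row per training row, one column per
#'   class of `levels(y)`; every row scored by the model not trained on its
#'   fold), `models` (k `cpi_learner_fit`s), `folds` (fold id per row).
#' @export
oof_scores <- function(X, y, spec, k = 10L, seed = 1L) {
  stopifnot(is.matrix(X), is.factor(y), nrow(X) == length(y))
  folds <- stratified_folds(y, k = k, seed = seed)
  oof <- matrix(NA_real_, nrow(X), nlevels(y),
                dimnames = list(NULL, levels(y)))
  models <- vector("list", k)
  for (f in seq_len(k)) {
    hold <- folds == f
    models[[f]] <- learner_fit(spec, X[!hold, , drop = FALSE], y[!hold])
    if (any(hold)) {
      oof[hold, ] <- learner_predict(models[[f]], X[hold, , drop = FALSE])
    }
  }
  list(oof = oof, models = models, folds = folds)
}

#' Fold-averaged scores for new data
#'
#' Implements the prediction-side counterpart of out-of-fold training:
#' every fold model predicts the new rows and the k score matrices are
#' averaged.
#'
#' @param models List of `cpi_learner_fit` fold models.
#' @param X New-data feature matrix (fit-time columns).
#' @return Averaged class-score matrix.
#' @export
predict_meta <- function(models, X) {
  stopifnot(length(models) >= 1L)
  acc <- NULL
  for (m in models) {
    p <- learner_predict(m, X)
    acc <- if (is.null(acc)) p else acc + p
  }
  acc / length(models)
}

#' Rank-normalize a score vector to the unit interval
#'
#' `(rank - 1) / (n - 1)` with average ranks for ties; order preserving; a
#' single score maps to 0.5.
#'
#' @param scores Finite numeric vector.
#' @return Numeric vector in `[0, 1]`.
#' @export
rank_normalize <- function(scores) {
  stopifnot(all(is.finite(scores)))
  n <- length(scores)
  if (n == 0L) return(numeric(0))
  if (n == 1L) return(0.5)
  (rank(scores, ties.method = "average") - 1) / (n - 1)
}

.micro_f1_labels <- function(truth, pred, positive_classes) {
  tp <- sum(truth == pred & truth %in% positive_classes)
  npred <- sum(pred %in% positive_classes)
  ngold <- sum(truth %in% positive_classes)
  p <- if (npred > 0) tp / npred else 0
  r <- if (ngold > 0) tp / ngold else 0
  if (p + r > 0) 2 * p * r / (p + r) else 0
}

.cv_f1 <- function(spec, X, y, cv, seed, positive_classes) {
  folds <- stratified_folds(y, k = cv, seed = seed)
  scores <- numeric(cv)
  for (f in seq_len(cv)) {
    hold <- folds == f
    fit <- learner_fit(spec, X[!hold, , drop = FALSE], y[!hold])
    prob <- learner_predict(fit, X[hold, , drop = FALSE])
    pred <- colnames(prob)[max.col(prob, ties.method = "first")]
    scores[f] <- .micro_f1_labels(as.character(y[hold]), pred,
                                  positive_classes)
  }
  mean(scores)
}

.hp_space <- function(family) {
  switch(family,
    rf = ,
    et = function() list(num.trees = sample(c(50L, 100L, 200L, 300L), 1L),
                         min.node.size = sample(c(1L, 2L, 5L, 10L), 1L)),
    xgb = function() list(nrounds = sample(c(20L, 40L, 80L, 150L), 1L),
                          max_depth = sample(2:8, 1L),
                          eta = stats::runif(1, 0.05, 0.5),
                          subsample = stats::runif(1, 0.6, 1),
                          colsample_bytree = stats::runif(1, 0.6, 1),
                          min_child_weight = sample(c(1, 3, 5), 1L)),
    lr = function() list(decay = 10^stats::runif(1, -5, 0)),
    lda = function() list(tol = 1e-8),
    nb = function() list(laplace = stats::runif(1, 0, 3)),
    function() list())
}

#' Randomized hyper-parameter search
#'
#' Samples `n_settings` hyper-parameter settings from the family's
#' distribution and scores each by `cv`-fold cross-validated F1 (binary F1
#' for two-class responses, micro-averaged F1 over the evaluated CPR
#' classes for multiclass); the best mean score wins. Deterministic for a
#' fixed seed.
#'
#' @param spec A [make_learner()] specification (its family fixes the
#'   sampling distribution).
#' @param X,y Training matrix and factor response.
#' @param n_settings Number of sampled settings (default 10).
#' @param cv Cross-validation folds (default 3).
#' @param seed Integer seed.
#' @param positive_classes Classes counted by the F1 criterion; defaults to
#'   the evaluated CPR groups for multiclass and the second level for
#'   binary responses.
#' @return List: `best_params`, `best_score`, `trace` (data.frame of
#'   settings and scores).
#' @export
randomized_search <- function(spec, X, y, n_settings = 10L, cv = 3L,
                              seed = 1L, positive_classes = NULL) {
  if (n_settings < 1L) stop("n_settings must be >= 1", call. = FALSE)
  if (is.null(positive_classes)) {
    positive_classes <- if (nlevels(y) == 2L) levels(y)[2L]
    else intersect(levels(y), as.character(CPR_EVALUATED))
  }
  sampler <- .hp_space(spec$family)
  settings <- vector("list", n_settings)
  set.seed(seed)
  for (i in seq_len(n_settings)) settings[[i]] <- sampler()
  scores <- numeric(n_settings)
  for (i in seq_len(n_settings)) {
    s <- make_learner(spec$family, settings[[i]], seed = spec$seed)
    scores[i] <- .cv_f1(s, X, y, cv, seed + i, positive_classes)
  }
  best <- which.max(scores)
  list(best_params = settings[[best]], best_score = scores[best],
       trace = data.frame(setting = seq_len(n_settings), score = scores))
}

#' Recursive feature elimination
#'
#' Repeatedly drops the least-important `step` fraction of the remaining
#' features (by the learner's own importances on the full data) and scores
#' every visited subset size by `cv`-fold cross-validated F1; returns the
#' subset with the best mean score. Deterministic for a fixed seed.
#'
#' @param spec A [make_learner()] specification; its family must expose
#'   importances (see [learner_importance()]).
#' @param X,y Training matrix and factor response.
#' @param cv Cross-validation folds (default 3).
#' @param seed Integer seed.
#' @param step Fraction of remaining features dropped per iteration
#'   (at least one); default 0.2.
#' @param min_features Stop once this many features remain (default 1).
#' @param positive_classes As in [randomized_search()].
#' @return List: `selected` (character vector of retained column names),
#'   `trace` (data.frame: subset size, CV score).
#' @export
rfe_select <- function(spec, X, y, cv = 3L, seed = 1L, step = 0.2,
                       min_features = 1L, positive_classes = NULL) {
  if (is.null(positive_classes)) {
    positive_classes <- if (nlevels(y) == 2L) levels(y)[2L]
    else intersect(levels(y), as.character(CPR_EVALUATED))
  }
  cols <- colnames(X)
  subsets <- list(cols)
  while (length(cols) > min_features) {
    fit <- learner_fit(spec, X[, cols, drop = FALSE], y)
    imp <- learner_importance(fit)
    ndrop <- max(1L, floor(step * length(cols)))
    ndrop <- min(ndrop, length(cols) - min_features)
    # ties broken by column order for determinism
    ord <- order(imp, seq_along(imp))
    drop <- names(imp)[ord][seq_len(ndrop)]
    cols <- setdiff(cols, drop)
    subsets[[length(subsets) + 1L]] <- cols
  }
  scores <- vapply(seq_along(subsets), function(i) {
    .cv_f1(spec, X[, subsets[[i]], drop = FALSE], y, cv, seed,
           positive_classes)
  }, numeric(1))
  best <- which.max(scores)
  list(selected = subsets[[best]],
       trace = data.frame(size = lengths(subsets), score = scores))
}

#' Choose the representative triplet of a CPI pair
#'
#' A pair with several interaction words yields several triplets; the one
#' whose largest evaluated-class score is highest represents the pair in
#' stage III. Ties are broken by the earlier interaction-word position,
#' then by the lexicographically smaller word.
#'
#' @param scores Numeric matrix of class scores (rows = the pair's
#'   triplets; columns named by class).
#' @param iw_index Interaction-word token positions, aligned with rows.
#' @param word Interaction-word surfaces, aligned with rows.
#' @param eval_classes Classes over which the row maximum is taken.
#' @return The selected row index.
#' @export
select_best_triplet <- function(scores, iw_index, word,
                                eval_classes = as.character(CPR_EVALUATED)) {
  if (is.null(dim(scores)) || !nrow(scores)) {
    stop("select_best_triplet needs at least one triplet row", call. = FALSE)
  }
  use <- intersect(colnames(scores), eval_classes)
  best <- apply(scores[, use, drop = FALSE], 1L, max)
  ord <- order(-best, iw_index, word, method = "radix")
  ord[1L]
}
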