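#' @title Base learners
#' @description A thin uniform interface over the base classifier families
#'   used by the three-stage model: random forest and extremely randomized
#'   trees (ranger), gradient-boosted trees (xgboost), multinomial logistic
#'   regression (nnet), linear discriminant analysis (MASS) and naive Bayes
#'   (e1071). Every family fits from a numeric feature matrix and a factor
#'   response and predicts a class-probability matrix over the full class
#'   list, so stages can treat them interchangeably. A `custom` family
#'   accepts user fit/predict closures (used, e.g., by leakage canaries).
#' @details The learner namespaces are imported (not just `::`-referenced)
#'   so their S3 `predict` methods are registered as soon as this package
#'   loads: a deserialized model bundle must predict without any prior fit
#'   call.
#' @name learners
#' @importFrom ranger ranger
#' @importFrom xgboost xgb.train
#' @importFrom nnet multinom
#' @importFrom MASS lda
#' @importFrom e1071 naiveBayes
NULL

LEARNER_FAMILIES <- c("rf", "et", "xgb", "lr", "lda", "nb", "custom")

#' Define a base learner
#'
#' @param family One of `"rf"` (random forest), `"et"` (extremely
#'   randomized trees), `"xgb"` (gradient-boosted trees), `"lr"` (logistic
#'   regression), `"lda"` (linear discriminant analysis), `"nb"` (naive
#'   Bayes) or `"custom"`.
#' @param params Named list of hyper-parameters (family-specific; see
#'   [default_hyperparameters()]). For `custom`: `fit = function(X, y)` and
#'   `predict = function(model, X)` returning a probability matrix.
#' @param seed Integer seed used for every stochastic step of fitting.
#' @return A `cpi_learner` specification.
#' @export
make_learner <- function(family, params = list(), seed = 1L) {
  family <- match.arg(family, LEARNER_FAMILIES)
  params <- utils::modifyList(default_hyperparameters(family), params)
  structure(list(family = family, params = params, seed = as.integer(seed)),
            class = "cpi_learner")
}

#' Default hyper-parameters per learner family
#'
#' Kept deliberately modest: the candidate sets this package trains on are
#' small relative to the feature count, and the stacked design gains more
#' from out-of-fold diversity than from deep individual models.
#'
#' @param family Learner family name.
#' @return Named list.
#' @export
default_hyperparameters <- function(family) {
  switch(family,
    rf = list(num.trees = 100L, min.node.size = 1L),
    et = list(num.trees = 100L, min.node.size = 1L),
    xgb = list(nrounds = 40L, max_depth = 4L, eta = 0.3, subsample = 1,
               colsample_bytree = 1, min_child_weight = 1),
    lr = list(decay = 1e-3, maxit = 200L),
    lda = list(tol = 1e-8),
    nb = list(laplace = 1),
    custom = list(),
    list())
}

.lda_keep_cols <- function(X, y, tol) {
  ok <- logical(ncol(X))
  for (j in seq_len(ncol(X))) {
    wss <- tapply(X[, j], y, stats::var)
    ok[j] <- isTRUE(stats::var(X[, j]) > tol) &&
      any(!is.na(wss) & wss > tol)
  }
  which(ok)
}

#' Fit a base learner
#'
#' @param spec A `cpi_learner`.
#' @param X Numeric feature matrix with column names.
#' @param y Factor response; its levels define the class list.
#' @return A `cpi_learner_fit` holding the fitted model and class list.
#' @export
learner_fit <- function(spec, X, y) {
  stopifnot(inherits(spec, "cpi_learner"), is.factor(y),
            is.matrix(X), nrow(X) == length(y))
  if (length(unique(as.character(y))) < 2L) {
    stop("degenerate fit: the response has a single class", call. = FALSE)
  }
  p <- spec$params
  set.seed(spec$seed)
  model <- switch(spec$family,
    rf = ranger::ranger(x = as.data.frame(X), y = droplevels(y),
                        probability = TRUE, num.trees = p$num.trees,
                        min.node.size = p$min.node.size,
                        importance = "impurity",
                        seed = spec$seed, num.threads = 1L),
    et = ranger::ranger(x = as.data.frame(X), y = droplevels(y),
                        probability = TRUE, num.trees = p$num.trees,
                        min.node.size = p$min.node.size,
                        splitrule = "extratrees", replace = FALSE,
                        sample.fraction = 1, importance = "impurity",
                        seed = spec$seed, num.threads = 1L),
    xgb = {
      yy <- droplevels(y)
      k <- nlevels(yy)
      lab <- as.integer(yy) - 1L
      dtrain <- xgboost::xgb.DMatrix(X, label = lab)
      pars <- list(max_depth = p$max_depth, eta = p$eta,
                   subsample = p$subsample,
                   colsample_bytree = p$colsample_bytree,
                   min_child_weight = p$min_child_weight,
                   nthread = 1L, seed = spec$seed)
      if (k == 2L) {
        pars$objective <- "binary:logistic"
      } else {
        pars$objective <- "multi:softprob"
        pars$num_class <- k
      }
      bst <- xgboost::xgb.train(params = pars, data = dtrain,
                                nrounds = p$nrounds, verbose = 0)
      list(booster = bst, k = k)
    },
    lr = {
      df <- as.data.frame(X)
      df$.y <- droplevels(y)
      utils::capture.output(
        fit <- nnet::multinom(.y ~ ., data = df, trace = FALSE,
                              maxit = p$maxit, decay = p$decay,
                              MaxNWts = 1e6))
      fit
    },
    lda = {
      keep <- .lda_keep_cols(X, droplevels(y), p$tol)
      if (!length(keep)) {
        stop("linear discriminant analysis: no usable (non-constant) ",
             "features", call. = FALSE)
      }
      fit <- suppressWarnings(MASS::lda(X[, keep, drop = FALSE],
                                        grouping = droplevels(y)))
      list(lda = fit, keep = keep)
    },
    nb = e1071::naiveBayes(as.data.frame(X), droplevels(y),
                           laplace = p$laplace),
    custom = p$fit(X, y))
  structure(list(spec = spec, model = model, classes = levels(y),
                 trained_levels = levels(droplevels(y)),
                 columns = colnames(X)),
            class = "cpi_learner_fit")
}

.align_prob <- function(prob, trained_levels, classes) {
  if (is.null(dim(prob))) prob <- matrix(prob, ncol = length(trained_levels))
  if (is.null(colnames(prob))) colnames(prob) <- trained_levels
  out <- matrix(0, nrow = nrow(prob), ncol = length(classes),
                dimnames = list(NULL, classes))
  common <- intersect(colnames(prob), classes)
  out[, common] <- prob[, common, drop = FALSE]
  out[!is.finite(out)] <- 0
  out
}

#' Predict class probabilities from a fitted base learner
#'
#' @param fit A `cpi_learner_fit`.
#' @param X Numeric matrix with the fit-time columns.
#' @return Matrix `nrow(X)` x number of classes, columns named by the full
#'   class list of the training response (classes absent from training
#'   score 0).
#' @export
learner_predict <- function(fit, X) {
  stopifnot(inherits(fit, "cpi_learner_fit"))
  if (!identical(colnames(X), fit$columns)) {
    if (!all(fit$columns %in% colnames(X))) {
      stop("feature registry mismatch between fit and predict", call. = FALSE)
    }
    X <- X[, fit$columns, drop = FALSE]
  }
  if (!nrow(X)) {
    return(matrix(0, 0, length(fit$classes),
                  dimnames = list(NULL, fit$classes)))
  }
  lv <- fit$trained_levels
  prob <- switch(fit$spec$family,
    rf = ,
    et = stats::predict(fit$model, data = as.data.frame(X),
                        num.threads = 1L)$predictions,
    xgb = {
      raw <- stats::predict(fit$model$booster, xgboost::xgb.DMatrix(X))
      if (fit$model$k == 2L) {
        cbind(1 - raw, raw)
      } else {
        matrix(raw, ncol = fit$model$k, byrow = TRUE)
      }
    },
    lr = {
      pr <- stats::predict(fit$model, newdata = as.data.frame(X),
                           type = "probs")
      if (is.null(dim(pr))) {
        if (length(lv) == 2L) cbind(1 - pr, pr) else matrix(pr, nrow = 1L)
      } else pr
    },
    lda = stats::predict(fit$model$lda,
                         X[, fit$model$keep, drop = FALSE])$posterior,
    nb = stats::predict(fit$model, as.data.frame(X), type = "raw",
                        threshold = 1e-3, eps = 1e-3),
    custom = fit$spec$params$predict(fit$model, X))
  if (is.null(colnames(prob))) colnames(prob) <- lv
  .align_prob(prob, lv, fit$classes)
}

#' Feature importances of a fitted base learner
#'
#' Used by recursive feature elimination. Tree families report impurity /
#' gain importance; logistic regression the summed absolute coefficients;
#' linear discriminant analysis the summed absolute discriminant loadings.
#'
#' @param fit A `cpi_learner_fit`.
#' @return Named numeric vector over the fit-time columns (higher = more
#'   important).
#' @export
learner_importance <- function(fit) {
  cols <- fit$columns
  imp <- rep(0, length(cols)); names(imp) <- cols
  v <- switch(fit$spec$family,
    rf = ,
    et = ranger::importance(fit$model),
    xgb = {
      tab <- xgboost::xgb.importance(model = fit$model$booster)
      stats::setNames(tab$Gain, tab$Feature)
    },
    lr = {
      co <- stats::coef(fit$model)
      if (is.null(dim(co))) co <- matrix(co, nrow = 1L,
                                         dimnames = list(NULL, names(co)))
      co <- co[, setdiff(colnames(co), "(Intercept)"), drop = FALSE]
      colSums(abs(co))[make.names(cols)[make.names(cols) %in%
                                          colnames(co)]]
    },
    lda = {
      sc <- fit$model$lda$scaling
      stats::setNames(rowSums(abs(sc)), cols[fit$model$keep])
    },
    nb = stop("naive Bayes exposes no importances; use a surrogate family ",
              "(e.g. 'rf') for feature elimination", call. = FALSE),
    custom = stop("custom learners expose no importances", call. = FALSE))
  v <- v[!is.na(names(v))]
  # multinom mangles non-syntactic column names; map back
  if (fit$spec$family == "lr") {
    names(v) <- cols[match(names(v), make.names(cols))]
    v <- v[!is.na(names(v))]
  }
  hit <- intersect(names(v), cols)
  imp[hit] <- v[hit]
  imp
}
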