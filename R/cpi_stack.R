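#' @title The three-stage CPI extraction model
#' @name cpi_stack_model
#' @description
#' `cpi_stack()` fits the full three-stage stacked-generalization model on a
#' ChemProt-style corpus and returns a fitted-model object with the usual
#' `print`/`summary`/`predict` methods.
#'
#' **Stage I** trains three binary base models (random forest, extremely
#' randomized trees, gradient-boosted trees) on the CPI-pair and
#' CPI-triplet tracks in parallel to score whether a candidate belongs to
#' any evaluated CPR group (3/4/5/6/9). Their rank-normalized out-of-fold
#' scores join the feature set of the next stage.
#'
#' **Stage II** trains six multiclass base models per track (the three tree
#' families plus logistic regression, linear discriminant analysis and
#' naive Bayes) over the six-class space CPR:3/4/5/6/9/other. Each model
#' contributes its six out-of-fold class scores plus its argmax class as
#' meta-features. A pair with several triplets is represented by the
#' triplet whose best evaluated-class score is highest.
#'
#' **Stage III** combines the original pair features with the stage-II
#' outputs of both tracks and fits logistic regression, random forest,
#' extremely randomized trees and gradient-boosted trees; their class
#' scores are averaged and the argmax is the final prediction. Pairs
#' predicted "other" are not emitted.
NULL

CLASSES6 <- c("3", "4", "5", "6", "9", "other")
STAGE1_FAMILIES <- c("rf", "et", "xgb")
STAGE2_FAMILIES <- c("rf", "et", "xgb", "lr", "lda", "nb")
STAGE3_FAMILIES <- c("lr", "rf", "et", "xgb")

.to_class6 <- function(labels) {
  factor(ifelse(labels %in% CPR_EVALUATED, as.character(labels), "other"),
         levels = CLASSES6)
}

.class_code <- function(cls) {
  unname(c("3" = 3, "4" = 4, "5" = 5, "6" = 6, "9" = 9, "other" = 10)[cls])
}

.s1_col <- function(fam) paste0("s1_", fam)
.s2_cols <- function(fam) {
  c(paste0("s2_", fam, "_", CLASSES6), paste0("s2_", fam, "_argmax"))
}

.stage2_block <- function(prob_by_fam) {
  blocks <- lapply(names(prob_by_fam), function(fam) {
    prob <- prob_by_fam[[fam]]
    am <- if (nrow(prob)) {
      .class_code(colnames(prob)[max.col(prob, ties.method = "first")])
    } else numeric(0)
    b <- cbind(prob, am)
    colnames(b) <- .s2_cols(fam)
    b
  })
  do.call(cbind, blocks)
}

.maybe_search <- function(spec, X, y, enabled, n_settings, cv, seed) {
  if (!enabled) return(spec)
  rs <- randomized_search(spec, X, y, n_settings = n_settings, cv = cv,
                          seed = seed)
  make_learner(spec$family, rs$best_params, seed = spec$seed)
}

.maybe_rfe <- function(spec, X, y, enabled, cv, seed) {
  if (!enabled || spec$family %in% c("nb", "custom")) return(colnames(X))
  rfe_select(spec, X, y, cv = cv, seed = seed)$selected
}

#' Fit the three-stage CPI extraction model
#'
#' @param corpus A `chemprot_corpus` with relation annotations (the
#'   training labels).
#' @param dictionary Interaction-word dictionary data.frame (columns
#'   `word`, `cpr`) or a path readable by [read_interaction_dictionary()].
#' @param parser Parser adapter: `function(tokens) -> dep_graph` (see
#'   [parser_from_fixtures()]).
#' @param folds Out-of-fold count per stage (default 10).
#' @param seed Integer master seed; fixes fold splits and every stochastic
#'   learner.
#' @param tracks Candidate tracks to use; default both `"pair"` and
#'   `"triplet"`. A corpus yielding no triplets degrades to pairs-only.
#' @param use_stage1 Append stage-I meta-features to the stage-II inputs
#'   (default TRUE; FALSE reproduces the without-stage-I ablation).
#' @param stage2_families Stage-II base-model families (default all six;
#'   set to `c("lr", "lda", "nb")` to drop the stage-I families).
#' @param search Run randomized hyper-parameter search per learner per
#'   track at each stage (default FALSE).
#' @param rfe Run recursive feature elimination per learner per track
#'   (default FALSE; naive Bayes is skipped, having no importances).
#' @param n_settings,search_cv Randomized-search budget (default 10
#'   settings, 3-fold CV).
#' @param hyperparameters Named list of per-family parameter overrides,
#'   e.g. `list(rf = list(num.trees = 300))`.
#' @param feature_config A [cpi_feature_config()].
#' @param stem Enable dictionary suffix-stemming (see
#'   [match_interaction_words()]).
#' @return A fitted `cpi_stack` object.
#' @seealso [predict.cpi_stack()], [save_cpi_stack()]
#' @export
cpi_stack <- function(corpus, dictionary, parser, folds = 10L, seed = 1L,
                      tracks = c("pair", "triplet"), use_stage1 = TRUE,
                      stage2_families = STAGE2_FAMILIES, search = FALSE,
                      rfe = FALSE, n_settings = 10L, search_cv = 3L,
                      hyperparameters = list(),
                      feature_config = cpi_feature_config(), stem = FALSE) {
  stopifnot(inherits(corpus, "chemprot_corpus"))
  if (is.character(dictionary)) {
    dictionary <- read_interaction_dictionary(dictionary)
  }
  tracks <- match.arg(tracks, c("pair", "triplet"), several.ok = TRUE)
  if (!"pair" %in% tracks) {
    stop("the pair track is the backbone of stage III and cannot be ",
         "disabled", call. = FALSE)
  }
  seed <- as.integer(seed)
  cands <- build_candidates(corpus, dictionary, stem = stem)
  if (!nrow(cands$pairs)) stop("corpus yields no candidate pairs",
                               call. = FALSE)
  if ("triplet" %in% tracks && !nrow(cands$triplets)) {
    message("no candidate triplets (empty dictionary match); ",
            "degrading to the pair track only")
    tracks <- "pair"
  }

  enc <- list(); registries <- list()
  for (tr in tracks) {
    e <- encode_matrix(cands, parser, track = tr, config = feature_config)
    enc[[tr]] <- e$X
    registries[[tr]] <- e$registry
  }

  labels <- list(pair = cands$pairs$label,
                 triplet = cands$triplets$label)
  hp <- function(fam) {
    if (!is.null(hyperparameters[[fam]])) hyperparameters[[fam]] else list()
  }

  # ---- Stage I: binary (evaluated CPR vs not), OOF rank-normalized scores
  stage1 <- list()
  Xaug <- list()
  for (tr in tracks) {
    y_bin <- factor(labels[[tr]] %in% CPR_EVALUATED,
                    levels = c(FALSE, TRUE), labels = c("neg", "pos"))
    if (length(unique(y_bin)) < 2L) {
      stop("stage I degenerate fit on the ", tr, " track: all candidates ",
           "share one binary label", call. = FALSE)
    }
    meta <- matrix(0, nrow(enc[[tr]]), length(STAGE1_FAMILIES),
                   dimnames = list(NULL, vapply(STAGE1_FAMILIES, .s1_col,
                                                character(1))))
    st <- list()
    for (i in seq_along(STAGE1_FAMILIES)) {
      fam <- STAGE1_FAMILIES[i]
      sd_i <- seed + 1000L * i + ifelse(tr == "pair", 0L, 100L)
      spec <- make_learner(fam, hp(fam), seed = sd_i)
      cols <- .maybe_rfe(spec, enc[[tr]], y_bin, rfe, search_cv, sd_i)
      spec <- .maybe_search(spec, enc[[tr]][, cols, drop = FALSE], y_bin,
                            search, n_settings, search_cv, sd_i)
      oo <- oof_scores(enc[[tr]][, cols, drop = FALSE], y_bin, spec,
                       k = folds, seed = sd_i)
      raw <- oo$oof[, "pos"]
      meta[, .s1_col(fam)] <- rank_normalize(raw)
      st[[fam]] <- list(models = oo$models, folds = oo$folds,
                        oof_raw = raw, columns = cols)
    }
    stage1[[tr]] <- st
    Xaug[[tr]] <- if (use_stage1) cbind(enc[[tr]], meta) else enc[[tr]]
  }

  # ---- Stage II: six-class multiclass per track
  stage2 <- list()
  s2_prob <- list()
  for (tr in tracks) {
    y6 <- .to_class6(labels[[tr]])
    if (length(unique(as.character(y6))) < 2L) {
      stop("stage II degenerate fit on the ", tr, " track", call. = FALSE)
    }
    st <- list(); probs <- list()
    for (i in seq_along(stage2_families)) {
      fam <- stage2_families[i]
      sd_i <- seed + 2000L * i + ifelse(tr == "pair", 0L, 100L)
      spec <- make_learner(fam, hp(fam), seed = sd_i)
      cols <- .maybe_rfe(spec, Xaug[[tr]], y6, rfe, search_cv, sd_i)
      spec <- .maybe_search(spec, Xaug[[tr]][, cols, drop = FALSE], y6,
                            search, n_settings, search_cv, sd_i)
      oo <- oof_scores(Xaug[[tr]][, cols, drop = FALSE], y6, spec,
                       k = folds, seed = sd_i)
      st[[fam]] <- list(models = oo$models, folds = oo$folds, columns = cols)
      probs[[fam]] <- oo$oof
    }
    stage2[[tr]] <- st
    s2_prob[[tr]] <- probs
  }

  # ---- Triplet selection + stage III assembly
  asm <- .assemble_stage3(cands, enc, s2_prob, tracks)
  y6_pair <- .to_class6(labels$pair)
  stage3 <- list()
  for (i in seq_along(STAGE3_FAMILIES)) {
    fam <- STAGE3_FAMILIES[i]
    sd_i <- seed + 3000L * i
    spec <- make_learner(fam, hp(fam), seed = sd_i)
    stage3[[fam]] <- learner_fit(spec, asm$X3, y6_pair)
  }

  structure(list(
    registries = registries, stage1 = stage1, stage2 = stage2,
    stage3 = stage3, tracks = tracks, use_stage1 = use_stage1,
    stage2_families = stage2_families, folds = folds, seed = seed,
    classes = CLASSES6, dictionary = dictionary, stem = stem,
    feature_config = feature_config,
    stage3_columns = colnames(asm$X3),
    training = list(n_pairs = nrow(cands$pairs),
                    n_triplets = nrow(cands$triplets),
                    label_table = table(factor(labels$pair, levels = 1:10)),
                    coverage = cands$coverage),
    call = match.call()),
    class = "cpi_stack")
}

# Combine pair features, the pair-track stage-II block and the selected
# triplet's stage-II block (zero-filled, flagged, for pairs with no
# triplet) into the stage-III design matrix.
.assemble_stage3 <- function(cands, enc, s2_prob, tracks) {
  pair_block <- .stage2_block(s2_prob$pair)
  parts <- list(enc$pair, pair_block)
  sel <- rep(NA_integer_, nrow(cands$pairs))
  if ("triplet" %in% tracks) {
    trip_block <- .stage2_block(s2_prob$triplet)
    mean_prob <- Reduce(`+`, s2_prob$triplet) / length(s2_prob$triplet)
    t3 <- matrix(0, nrow(cands$pairs), ncol(trip_block) + 1L,
                 dimnames = list(NULL, c(paste0("trip_",
                                                colnames(trip_block)),
                                         "no_triplet")))
    t3[, "no_triplet"] <- 1
    for (pid in unique(cands$triplets$pair_id)) {
      rows <- which(cands$triplets$pair_id == pid)
      j <- select_best_triplet(mean_prob[rows, , drop = FALSE],
                               cands$triplets$iw_index[rows],
                               cands$triplets$word[rows])
      r <- rows[j]
      i <- match(pid, cands$pairs$pair_id)
      sel[i] <- r
      t3[i, seq_len(ncol(trip_block))] <- trip_block[r, ]
      t3[i, "no_triplet"] <- 0
    }
    parts <- c(parts, list(t3))
  }
  list(X3 = do.call(cbind, parts), selected_triplet = sel)
}

#' @export
print.cpi_stack <- function(x, ...) {
  cat("Three-stage stacked CPI extraction model\n")
  cat("  tracks:", paste(x$tracks, collapse = " + "),
      "| folds:", x$folds, "| seed:", x$seed, "\n")
  cat("  trained on", x$training$n_pairs, "CPI pairs and",
      x$training$n_triplets, "CPI triplets\n")
  cat("  stage II families:", paste(x$stage2_families, collapse = ", "),
      if (x$use_stage1) "(with stage-I meta-features)" else
        "(without stage-I meta-features)", "\n")
  invisible(x)
}

#' @export
summary.cpi_stack <- function(object, ...) {
  out <- list(model = object,
              label_table = object$training$label_table,
              coverage = object$training$coverage)
  class(out) <- "summary.cpi_stack"
  out
}

#' @export
print.summary.cpi_stack <- function(x, ...) {
  print(x$model)
  cat("\nTraining pair labels by CPR group:\n")
  print(x$label_table)
  cov <- x$coverage
  cat("\nGold annotations:", cov$n_annotations, "(",
      cov$n_unreachable, "sentence-unreachable );",
      cov$n_repairs, "sentence-boundary repairs\n")
  invisible(x)
}

.stage1_meta_predict <- function(st, X) {
  meta <- matrix(0, nrow(X), length(st),
                 dimnames = list(NULL, vapply(names(st), .s1_col,
                                              character(1))))
  for (fam in names(st)) {
    raw <- predict_meta(st[[fam]]$models, X)[, "pos"]
    # map through the ECDF of the training OOF scores: batch-size
    # independent, order preserving, same [0,1] scale as the fit
    meta[, .s1_col(fam)] <- stats::ecdf(st[[fam]]$oof_raw)(raw)
  }
  meta
}

.stage2_prob_predict <- function(st, X) {
  probs <- list()
  for (fam in names(st)) {
    probs[[fam]] <- predict_meta(st[[fam]]$models, X)
  }
  probs
}

#' Predict CPIs for a corpus
#'
#' Rebuilds candidates and features for `corpus`, propagates them through
#' the three stages (test-side meta-features are fold-model averages; see
#' [predict_meta()]) and returns the extracted interactions.
#'
#' @param object A fitted `cpi_stack`.
#' @param corpus A `chemprot_corpus` (relations not required).
#' @param parser Parser adapter for the new corpus's masked sentences.
#' @param type `"records"` (default): deduplicated abstract-level
#'   interaction records (pmid, cpr, arg1, arg2, score), the unit the
#'   challenge evaluates; `"pairs"`: one row per candidate pair with the
#'   predicted class (including `"other"`), its score, and the averaged
#'   stage-III class-score matrix as an attribute.
#' @param ... Unused.
#' @return A data.frame (see `type`).
#' @export
predict.cpi_stack <- function(object, corpus, parser,
                              type = c("records", "pairs"), ...) {
  type <- match.arg(type)
  stopifnot(inherits(corpus, "chemprot_corpus"))
  cands <- build_candidates(corpus, object$dictionary, stem = object$stem)
  empty <- data.frame(pmid = character(), cpr = integer(),
                      arg1 = character(), arg2 = character(),
                      score = numeric(), stringsAsFactors = FALSE)
  if (!nrow(cands$pairs)) return(empty)

  enc <- list()
  for (tr in object$tracks) {
    if (tr == "triplet" && !nrow(cands$triplets)) next
    enc[[tr]] <- encode_matrix(cands, parser, track = tr,
                               registry = object$registries[[tr]],
                               config = object$feature_config)$X
  }

  s2_prob <- list()
  for (tr in names(enc)) {
    Xa <- if (object$use_stage1) {
      cbind(enc[[tr]], .stage1_meta_predict(object$stage1[[tr]], enc[[tr]]))
    } else enc[[tr]]
    s2_prob[[tr]] <- .stage2_prob_predict(object$stage2[[tr]], Xa)
  }
  if ("triplet" %in% object$tracks && is.null(enc$triplet)) {
    # corpus without any dictionary hit: all-zero triplet block, flag on
    s2_prob$triplet <- lapply(object$stage2$triplet, function(st)
      matrix(0, 0L, length(CLASSES6), dimnames = list(NULL, CLASSES6)))
    cands$triplets <- cands$triplets[0, , drop = FALSE]
  }
  asm <- .assemble_stage3(cands, enc, s2_prob,
                          intersect(object$tracks, c("pair",
                                                     names(s2_prob))))
  X3 <- asm$X3
  if (!identical(colnames(X3), object$stage3_columns)) {
    stop("stage III registry mismatch between fit and predict",
         call. = FALSE)
  }
  prob <- Reduce(`+`, lapply(object$stage3,
                             function(m) learner_predict(m, X3))) /
    length(object$stage3)
  cls <- colnames(prob)[max.col(prob, ties.method = "first")]
  score <- prob[cbind(seq_len(nrow(prob)), max.col(prob,
                                                   ties.method = "first"))]
  pairs <- cands$pairs
  pairs$pred_class <- cls
  pairs$score <- score
  if (type == "pairs") {
    attr(pairs, "class_scores") <- prob
    return(pairs)
  }
  keep <- cls != "other"
  if (!any(keep)) return(empty)
  rec <- data.frame(pmid = pairs$pmid[keep],
                    cpr = as.integer(cls[keep]),
                    arg1 = pairs$chem_term[keep],
                    arg2 = pairs$prot_term[keep],
                    score = score[keep], stringsAsFactors = FALSE)
  # abstract-level identity: a relation seen in several sentences counts once
  key <- paste(rec$pmid, rec$cpr, rec$arg1, rec$arg2, sep = "\r")
  rec <- rec[order(key, -rec$score), , drop = FALSE]
  rec <- rec[!duplicated(paste(rec$pmid, rec$cpr, rec$arg1, rec$arg2,
                               sep = "\r")), , drop = FALSE]
  rownames(rec) <- NULL
  rec
}

#' Save a fitted model bundle
#'
#' Writes a directory holding the serialized model plus a plain-text
#' manifest (package version, seed, tracks, families, class list) for
#' auditability.
#'
#' @param object A fitted `cpi_stack`.
#' @param dir Bundle directory (created if missing).
#' @return Invisibly, `dir`.
#' @export
save_cpi_stack <- function(object, dir) {
  stopifnot(inherits(object, "cpi_stack"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  manifest <- list(
    package = "cpistack",
    version = as.character(utils::packageVersion("cpistack")),
    seed = object$seed, folds = object$folds, tracks = object$tracks,
    use_stage1 = object$use_stage1,
    stage2_families = object$stage2_families, classes = object$classes)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  saveRDS(object, file.path(dir, "model.rds"))
  invisible(dir)
}

#' Load a model bundle written by [save_cpi_stack()]
#'
#' @param dir Bundle directory.
#' @return The `cpi_stack` object.
#' @export
load_cpi_stack <- function(dir) {
  path <- file.path(dir, "model.rds")
  if (!file.exists(path)) stop("not a model bundle: ", dir, call. = FALSE)
  obj <- readRDS(path)
  if (!inherits(obj, "cpi_stack")) stop("corrupt model bundle", call. = FALSE)
  obj
}
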