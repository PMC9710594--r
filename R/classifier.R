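# Class-weighted random-forest classifier for decoy scoring: training,
# importance-driven forward feature selection, coordinate-wise hyperparameter
# tuning, prediction and per-target ranking. The forest itself (CART/Gini,
# bootstrap, mtry = floor(sqrt(p))) lives in src/forest.cpp and is exposed
# here as plain data, so fitted models serialize to JSON.

#' Random-forest hyperparameters
#'
#' Defaults are the tuned reference values: 100 trees, minimum 10 samples to
#' split a node, class weights 1.2 (incorrect, class 0) and 0.1 (correct,
#' class 1).
#'
#' @param n_trees number of trees.
#' @param min_samples_split minimum node size eligible for splitting.
#' @param class_weight_incorrect,class_weight_correct per-class sample
#'   weights applied at fit time.
#' @param seed integer RNG seed for bootstrap and feature subsampling.
#' @return list of class `rf_hyperparameters`.
#' @export
hyperparameters <- function(n_trees = 100, min_samples_split = 10,
                            class_weight_incorrect = 1.2,
                            class_weight_correct = 0.1, seed = 1) {
  stopifnot(n_trees > 0, min_samples_split > 0,
            class_weight_incorrect > 0, class_weight_correct > 0)
  structure(list(n_trees = as.integer(n_trees),
                 min_samples_split = as.integer(min_samples_split),
                 class_weight_incorrect = class_weight_incorrect,
                 class_weight_correct = class_weight_correct,
                 seed = as.integer(seed)),
            class = "rf_hyperparameters")
}

# Coerce feature_table or matrix input to a numeric matrix over `features`.
.as_feature_matrix <- function(rows, features = NULL) {
  if (inherits(rows, "feature_table")) {
    feats <- features %||% registry_names(rows)
    missing <- setdiff(feats, registry_names(rows))
    if (length(missing) > 0L)
      stop("schema error: missing selected feature(s): ",
           paste(missing, collapse = ", "))
    feature_matrix(rows, feats)
  } else {
    m <- as.matrix(rows)
    if (!is.null(features)) {
      if (!all(features %in% colnames(m)))
        stop("schema error: missing selected feature(s)")
      m <- m[, features, drop = FALSE]
    }
    m
  }
}

#' Train a class-weighted random forest
#'
#' Features are Z-score normalized with statistics fit on the training rows
#' (or supplied via `normalization`); the stored statistics are re-applied at
#' prediction time. Class weights enter as per-sample weights. Deterministic
#' given `hp$seed`.
#'
#' @param features [feature_table()] or numeric matrix of training rows (no
#'   missing values).
#' @param labels binary vector (0 incorrect / 1 correct).
#' @param hp [hyperparameters()].
#' @param normalization optional pre-fit [fit_normalization()] statistics;
#'   `NULL` fits on `features`.
#' @param feature_names subset of features to train on (default: all).
#' @return object of class `trained_classifier` with elements `forest`
#'   (list of node tables), `selected_features`, `importances` (sums to 1),
#'   `normalization`, `hp`.
#' @export
train_forest <- function(features, labels, hp = hyperparameters(),
                         normalization = NULL, feature_names = NULL) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L)
    stop("degenerate-label error: training labels are single-class")
  m <- .as_feature_matrix(features, feature_names)
  if (anyNA(m)) stop("missing values in training features; impute first")
  if (nrow(m) != length(labels)) stop("features/labels length mismatch")
  if (is.null(normalization)) {
    mu <- colMeans(m); sigma <- apply(m, 2, sd)
    keep <- sigma > 0
    if (!any(keep)) stop("all features constant")
    if (any(!keep))
      warning("dropping constant feature(s): ",
              paste(colnames(m)[!keep], collapse = ", "))
    normalization <- list(mu = mu[keep], sigma = sigma[keep],
                          features = colnames(m)[keep])
  }
  feats <- normalization$features
  m <- m[, feats, drop = FALSE]
  m <- sweep(sweep(m, 2, normalization$mu[feats]), 2,
             normalization$sigma[feats], `/`)
  w <- ifelse(labels == 0L, hp$class_weight_incorrect,
              hp$class_weight_correct)
  mtry <- max(1L, floor(sqrt(ncol(m))))
  fit <- rf_fit_cpp(m, labels, w, hp$n_trees, hp$min_samples_split, mtry,
                    hp$seed)
  structure(list(forest = fit$trees,
                 selected_features = feats,
                 importances = setNames(fit$importance, feats),
                 normalization = normalization,
                 hp = hp),
            class = "trained_classifier")
}

#' @export
print.trained_classifier <- function(x, ...) {
  cat(sprintf(
    "<trained_classifier: %d trees, %d features; top: %s (%.3f)>\n",
    length(x$forest), length(x$selected_features),
    names(sort(x$importances, decreasing = TRUE))[1],
    max(x$importances)))
  invisible(x)
}

#' Predict decoy class and score
#'
#' The model's stored normalization is applied to the rows; the score is the
#' fraction of trees voting "correct" and the label is the majority vote
#' (correct iff score >= 0.5).
#'
#' @param object a `trained_classifier`.
#' @param rows [feature_table()] or matrix containing all selected features.
#' @param ... unused.
#' @return data.frame with `score` in \[0,1\] and `label` (0/1); when `rows`
#'   is a feature table, keyed by `target_id`, `model_id`.
#' @export
predict.trained_classifier <- function(object, rows, ...) {
  m <- .as_feature_matrix(rows, object$selected_features)
  nz <- object$normalization
  m <- sweep(sweep(m, 2, nz$mu[object$selected_features]), 2,
             nz$sigma[object$selected_features], `/`)
  score <- rf_predict_cpp(object$forest, m)
  out <- data.frame(score = score, label = as.integer(score >= 0.5))
  if (inherits(rows, "feature_table"))
    out <- cbind(rows[, c("target_id", "model_id")], out)
  rownames(out) <- NULL
  out
}

.val_mcc <- function(model, rows, labels) {
  p <- predict(model, rows)
  ms <- metrics(confusion(labels, p$label))
  c(acc = ms$Acc, mcc = ms$MCC)
}

#' Importance-driven forward feature selection
#'
#' Fits a full-feature forest on the training rows, ranks features by
#' impurity importance, then adds them one at a time from highest to lowest,
#' recording validation accuracy and MCC at each step. Returns the features
#' whose full-model importance reaches `importance_threshold` (top-1 with a
#' warning if none does) together with the metric trace.
#'
#' @param train_rows,val_rows [feature_table()]s (or matrices).
#' @param train_labels,val_labels binary label vectors.
#' @param importance_threshold minimum importance to keep a feature.
#' @param hp [hyperparameters()].
#' @return list: `selected` (ordered by importance), `trace` (data.frame
#'   `step`, `feature`, `importance`, `acc`, `mcc`), `importances`.
#' @export
forward_select <- function(train_rows, train_labels, val_rows, val_labels,
                           importance_threshold = 0.01,
                           hp = hyperparameters()) {
  full <- train_forest(train_rows, train_labels, hp)
  ranked <- sort(full$importances, decreasing = TRUE)
  trace <- vector("list", length(ranked))
  for (k in seq_along(ranked)) {
    sub <- train_forest(train_rows, train_labels, hp,
                        feature_names = names(ranked)[seq_len(k)])
    v <- .val_mcc(sub, val_rows, val_labels)
    trace[[k]] <- data.frame(step = k, feature = names(ranked)[k],
                             importance = unname(ranked[k]),
                             acc = v[["acc"]], mcc = v[["mcc"]])
  }
  selected <- names(ranked)[ranked >= importance_threshold]
  if (length(selected) == 0L) {
    warning("importance threshold excludes all features; keeping top-1")
    selected <- names(ranked)[1]
  }
  list(selected = selected, trace = do.call(rbind, trace),
       importances = full$importances)
}

#' Features common to several selection runs
#'
#' Set intersection of the selections, ordered by mean importance. An empty
#' intersection falls back (with a warning) to the union.
#'
#' @param selections list (length >= 2) of character vectors.
#' @param importances optional list of named importance vectors (parallel to
#'   `selections`) used for ordering.
#' @return character vector of feature names.
#' @export
select_common_features <- function(selections, importances = NULL) {
  stopifnot(length(selections) >= 2L)
  common <- Reduce(intersect, selections)
  if (length(common) == 0L) {
    warning("empty intersection of feature selections; using the union")
    common <- Reduce(union, selections)
  }
  if (!is.null(importances)) {
    all_names <- unique(unlist(lapply(importances, names)))
    imp <- sapply(common, function(f)
      mean(vapply(importances, function(v) v[f] %||% 0, numeric(1)),
           na.rm = TRUE))
    common <- common[order(-imp)]
  }
  common
}

#' Coordinate-wise hyperparameter tuning
#'
#' Each hyperparameter axis is scanned over its grid while the others are
#' held at their defaults; the value maximizing validation MCC wins. On a
#' tie the default value is preferred if tied, otherwise the smallest value.
#' The class-weight pair is treated as one axis.
#'
#' @inheritParams forward_select
#' @param grid list with any of `n_trees`, `min_samples_split` (numeric
#'   vectors) and `class_weights` (list of `c(incorrect, correct)` pairs).
#' @param defaults [hyperparameters()] used for the held-fixed axes.
#' @return tuned [hyperparameters()] with a `tuning_trace` attribute.
#' @export
tune_forest <- function(train_rows, train_labels, val_rows, val_labels,
                        grid, defaults = hyperparameters()) {
  stopifnot(length(grid) > 0L)
  score_hp <- function(hp) {
    fit <- train_forest(train_rows, train_labels, hp)
    .val_mcc(fit, val_rows, val_labels)[["mcc"]]
  }
  pick <- function(values, default, mccs, simpler) {
    best <- max(mccs)
    tied <- which(mccs >= best - 1e-12)
    di <- which(vapply(values, function(v) identical(v, default), logical(1)))
    if (length(di) == 1L && di %in% tied) return(values[[di]])
    values[[tied[order(vapply(tied, function(i) simpler(values[[i]]),
                              numeric(1)))[1]]]]
  }
  trace <- list()
  tuned <- defaults
  if (!is.null(grid$n_trees)) {
    mccs <- vapply(grid$n_trees, function(v) {
      hp <- defaults; hp$n_trees <- as.integer(v); score_hp(hp)
    }, numeric(1))
    tuned$n_trees <- as.integer(pick(as.list(as.integer(grid$n_trees)),
                                     defaults$n_trees, mccs, identity))
    trace$n_trees <- data.frame(value = grid$n_trees, mcc = mccs)
  }
  if (!is.null(grid$min_samples_split)) {
    mccs <- vapply(grid$min_samples_split, function(v) {
      hp <- defaults; hp$min_samples_split <- as.integer(v); score_hp(hp)
    }, numeric(1))
    tuned$min_samples_split <- as.integer(
      pick(as.list(as.integer(grid$min_samples_split)),
           defaults$min_samples_split, mccs, identity))
    trace$min_samples_split <- data.frame(value = grid$min_samples_split,
                                          mcc = mccs)
  }
  if (!is.null(grid$class_weights)) {
    mccs <- vapply(grid$class_weights, function(v) {
      hp <- defaults
      hp$class_weight_incorrect <- v[[1]]
      hp$class_weight_correct <- v[[2]]
      score_hp(hp)
    }, numeric(1))
    w <- pick(grid$class_weights,
              c(defaults$class_weight_incorrect,
                defaults$class_weight_correct),
              mccs, function(v) v[[1]] + v[[2]])
    tuned$class_weight_incorrect <- w[[1]]
    tuned$class_weight_correct <- w[[2]]
    trace$class_weights <- data.frame(
      incorrect = vapply(grid$class_weights, `[[`, numeric(1), 1),
      correct = vapply(grid$class_weights, `[[`, numeric(1), 2),
      mcc = mccs)
  }
  attr(tuned, "tuning_trace") <- trace
  tuned
}

#' Rank one target's decoys by classifier score
#'
#' Descending score; ties broken by CONSRANK score (when present in the
#' rows) and then lexicographically by model id.
#'
#' @param model a `trained_classifier`.
#' @param target_rows [feature_table()] rows of a single target.
#' @return character vector of model ids, best first.
#' @export
rank_decoys <- function(model, target_rows) {
  stopifnot(inherits(target_rows, "feature_table"))
  p <- predict(model, target_rows)
  consrank <- if ("CONSRANK_score" %in% registry_names(target_rows))
    as.data.frame(target_rows)$CONSRANK_score else rep(0, nrow(p))
  p$model_id[order(-p$score, -consrank, p$model_id)]
}

#' Save a trained classifier as JSON
#'
#' The whole model (tree node tables, selected features, normalization
#' statistics, hyperparameters) is plain data and round-trips losslessly.
#'
#' @param model a `trained_classifier`.
#' @param path output `.json` path.
#' @return `path`, invisibly.
#' @export
save_classifier <- function(model, path) {
  payload <- list(
    format = "decoyforest/rf-v1",
    selected_features = model$selected_features,
    importances = as.list(model$importances),
    normalization = list(mu = as.list(model$normalization$mu),
                         sigma = as.list(model$normalization$sigma),
                         features = model$normalization$features),
    hp = unclass(model$hp),
    forest = model$forest)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a classifier saved by [save_classifier()]
#'
#' @param path `.json` path.
#' @return a `trained_classifier`.
#' @export
load_classifier <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(p$format, "decoyforest/rf-v1"))
    stop("not a saved classifier: ", path)
  forest <- p$forest
  if (is.array(forest) && length(dim(forest)) == 3L)
    forest <- lapply(seq_len(dim(forest)[1]), function(i) forest[i, , ])
  hp <- hyperparameters(p$hp$n_trees, p$hp$min_samples_split,
                        p$hp$class_weight_incorrect,
                        p$hp$class_weight_correct, p$hp$seed)
  structure(list(forest = forest,
                 selected_features = p$selected_features,
                 importances = unlist(p$importances),
                 normalization = list(
                   mu = unlist(p$normalization$mu),
                   sigma = unlist(p$normalization$sigma),
                   features = p$normalization$features),
                 hp = hp),
            class = "trained_classifier")
}
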