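# End-to-end desk-scale pipeline on the synthetic world: simulate ->
# assess -> featurize -> build datasets -> train (forward selection) ->
# evaluate. This is the path the smoke tests and the acceptance script run.

#' Run the full pipeline on a synthetic world
#'
#' Generates natives and decoy ensembles, assesses them against the CAPRI
#' criteria, screens clashes, computes the internal feature set (consensus
#' contact score, contact-class counts, optionally surface terms), builds a
#' balanced training manifest and a capped unbalanced validation manifest,
#' trains a class-weighted forest with importance-driven forward selection,
#' and evaluates per-class metrics and the top-N success rate on the
#' held-out targets.
#'
#' @param spec a [synthetic_spec()].
#' @param select_threshold forward-selection importance threshold.
#' @param hp [hyperparameters()].
#' @param n_validation validation targets (target-level split).
#' @param total_3k,cap_correct_3k validation manifest sizes; desk-scale
#'   defaults are the ensemble size and a proportional cap (the reference
#'   full-scale values are 3000/600).
#' @param surface compute BSA/NIS surface features (slower).
#' @param n_points SASA discretization.
#' @param top_n success-rate depth.
#' @return list with `assessment`, `labeled`, `features`, `split`,
#'   `selection`, `model`, `validation_metrics`, `success`.
#' @export
run_synthetic_pipeline <- function(spec, select_threshold = 0.01,
                                   hp = hyperparameters(),
                                   n_validation = max(2L,
                                                      spec$n_targets %/% 4L),
                                   total_3k = sum(spec$tier_counts),
                                   cap_correct_3k = max(
                                     1L, sum(spec$tier_counts) %/% 5L),
                                   surface = TRUE, n_points = 960,
                                   top_n = 10) {
  worlds <- lapply(seq_len(spec$n_targets), function(i) {
    native <- make_native(spec, i)
    dec <- make_decoys(native, spec)
    assessment <- assess_target(native, dec$decoys)
    assessment$target_id <- native$target_id
    assessment$planted <- dec$planted
    list(native = native, decoys = dec$decoys, assessment = assessment)
  })
  assessment <- do.call(rbind, lapply(worlds, `[[`, "assessment"))
  labeled <- drop_targets_without_correct(labeled_decoy_set(assessment))

  features <- do.call(rbind, lapply(worlds, function(w)
    as.data.frame(featurize_target(w$decoys, surface = surface,
                                   n_points = n_points))))
  features <- feature_table(features)
  features <- clean_and_impute(features)

  targets <- unique(labeled$target_id)
  split <- repeated_random_splits(targets, n_validation = n_validation,
                                  repeats = 1, seed = spec$seed)[[1]]

  bal <- build_balanced(labeled, seed = spec$seed)
  val3k <- build_3k(labeled, seed = spec$seed, total = total_3k,
                    cap_correct = cap_correct_3k)

  key <- function(df) paste(df$target_id, df$model_id)
  pick_rows <- function(manifest, target_set) {
    m <- manifest[manifest$target_id %in% target_set, , drop = FALSE]
    idx <- match(key(m), key(features))
    list(rows = feature_table(as.data.frame(features)[idx, , drop = FALSE]),
         labels = m$label, manifest = m)
  }
  tr <- pick_rows(bal, split$train_targets)
  va_bal <- pick_rows(bal, split$validation_targets)
  va_3k <- pick_rows(val3k, split$validation_targets)

  selection <- forward_select(tr$rows, tr$labels, va_bal$rows, va_bal$labels,
                              importance_threshold = select_threshold,
                              hp = hp)
  model <- train_forest(tr$rows, tr$labels, hp,
                        feature_names = selection$selected)

  pred <- predict(model, va_3k$rows)
  vm <- metrics(confusion(va_3k$labels, pred$label))

  qual <- setNames(assessment$quality,
                   paste(assessment$target_id, assessment$model_id))
  rankings <- lapply(split$validation_targets, function(t) {
    rows <- feature_table(
      as.data.frame(va_3k$rows)[va_3k$rows$target_id == t, , drop = FALSE])
    rank_decoys(model, rows)
  })
  names(rankings) <- split$validation_targets
  qualities <- lapply(split$validation_targets, function(t) {
    m <- va_3k$manifest[va_3k$manifest$target_id == t, ]
    setNames(m$quality, m$model_id)
  })
  names(qualities) <- split$validation_targets
  success <- success_rate(rankings, qualities, N = top_n)

  list(assessment = assessment, labeled = labeled, features = features,
       split = split, selection = selection, model = model,
       validation_metrics = vm, success = success)
}
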