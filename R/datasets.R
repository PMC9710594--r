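# Dataset construction: per-target balanced undersampling (Bal) and the
# capped 3000-decoy unbalanced (3K) manifests, plus the two target-level
# train/validation split schemes. Splits are always by target, never by
# decoy, so no decoy of a validation target can leak into training.

# Deterministic 31-bit hash of a string; used to derive per-target RNG
# substreams so adding/removing a target never perturbs other targets'
# samples.
.str_hash <- function(s) {
  h <- 0
  for (k in utf8ToInt(s)) h <- (h * 31 + k) %% 2147483647
  as.integer(h)
}

.target_seed <- function(seed, target_id)
  as.integer((as.numeric(seed) + .str_hash(target_id)) %% 2147483647)

# Evaluate `expr` under a local, seeded RNG without touching the caller's
# RNG state.
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
          else if (exists(".Random.seed", .GlobalEnv))
            rm(".Random.seed", envir = .GlobalEnv))
  set.seed(seed)
  expr
}

#' Build a labeled decoy set from assessment results
#'
#' Applies the clash screen per target and attaches the binary label
#' (correct = acceptable, medium or high). Only clash-kept decoys are
#' eligible for any dataset.
#'
#' @param assessment data.frame as from [assess_target()] (possibly several
#'   targets row-bound) with a `target_id` column added, or with the
#'   attribute-carrying columns `model_id`, `quality`, `clashes`.
#' @return data.frame `target_id`, `model_id`, `quality`, `label`
#'   (0 incorrect / 1 correct), `clash_kept`.
#' @export
labeled_decoy_set <- function(assessment) {
  stopifnot(all(c("target_id", "model_id", "quality", "clashes") %in%
                  names(assessment)))
  a <- if ("error" %in% names(assessment))
    assessment[is.na(assessment$error), , drop = FALSE]
  else assessment
  out <- lapply(split(a, a$target_id), function(g) {
    scr <- screen_clashes(setNames(g$clashes, g$model_id))
    data.frame(target_id = g$target_id, model_id = g$model_id,
               quality = g$quality,
               label = as.integer(g$quality != "incorrect"),
               clash_kept = g$model_id %in% scr$kept_ids,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Remove targets with no correct decoy
#'
#' @param sets labeled decoy set ([labeled_decoy_set()]).
#' @return the set without targets lacking any clash-kept correct decoy;
#'   removals are messaged.
#' @export
drop_targets_without_correct <- function(sets) {
  ok <- tapply(sets$label == 1L & sets$clash_kept, sets$target_id, any)
  bad <- names(ok)[!ok]
  if (length(bad) > 0L)
    message("removing ", length(bad), " target(s) without correct decoys: ",
            paste(bad, collapse = ", "))
  out <- sets[!(sets$target_id %in% bad), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Balanced (1:1) per-target dataset manifest
#'
#' For each target, all clash-kept correct decoys plus an equal-size uniform
#' random sample (without replacement) of its clash-kept incorrect decoys.
#' If a target has fewer incorrect than correct decoys, all incorrect ones
#' are taken and the imbalance is messaged.
#'
#' @param sets labeled decoy set.
#' @param seed integer; per-target substreams are derived from it.
#' @param cap_correct optional cap on correct decoys per target (`Inf` by
#'   default; the unbalanced 3K builder always caps at 600).
#' @return manifest data.frame `target_id`, `model_id`, `quality`, `label`.
#' @export
build_balanced <- function(sets, seed, cap_correct = Inf) {
  sets <- sets[sets$clash_kept, , drop = FALSE]
  out <- lapply(split(sets, sets$target_id), function(g) {
    g <- g[order(g$model_id), , drop = FALSE]
    corr <- g[g$label == 1L, , drop = FALSE]
    inc <- g[g$label == 0L, , drop = FALSE]
    ts <- .target_seed(seed, g$target_id[1])
    if (nrow(corr) > cap_correct)
      corr <- .with_seed(ts + 1L,
                         corr[sample(nrow(corr), cap_correct), , drop = FALSE])
    k <- min(nrow(corr), nrow(inc))
    if (k < nrow(corr))
      message("target ", g$target_id[1], ": only ", nrow(inc),
              " incorrect decoys for ", nrow(corr), " correct")
    inc <- .with_seed(ts, inc[sample(nrow(inc), k), , drop = FALSE])
    rbind(corr, inc)
  })
  res <- do.call(rbind, out)[, c("target_id", "model_id", "quality", "label")]
  rownames(res) <- NULL
  res
}

#' Capped unbalanced ("3K") dataset manifest
#'
#' Per target: up to `cap_correct` (600) clash-kept correct decoys (uniform
#' random sample when over the cap), topped up with randomly sampled
#' incorrect decoys until `total` (3000) decoys. If supply is short, all
#' decoys are taken and the shortfall is messaged.
#'
#' @inheritParams build_balanced
#' @param total decoys per target.
#' @param cap_correct maximum correct decoys per target.
#' @return manifest data.frame `target_id`, `model_id`, `quality`, `label`.
#' @export
build_3k <- function(sets, seed, total = 3000, cap_correct = 600) {
  sets <- sets[sets$clash_kept, , drop = FALSE]
  out <- lapply(split(sets, sets$target_id), function(g) {
    g <- g[order(g$model_id), , drop = FALSE]
    corr <- g[g$label == 1L, , drop = FALSE]
    inc <- g[g$label == 0L, , drop = FALSE]
    ts <- .target_seed(seed, g$target_id[1])
    if (nrow(corr) > cap_correct)
      corr <- .with_seed(ts + 1L,
                         corr[sample(nrow(corr), cap_correct), , drop = FALSE])
    need <- total - nrow(corr)
    if (need > nrow(inc)) {
      message("target ", g$target_id[1], ": only ",
              nrow(inc) + nrow(corr), " decoys available for total ", total)
      need <- nrow(inc)
    }
    inc <- .with_seed(ts + 2L, inc[sample(nrow(inc), need), , drop = FALSE])
    rbind(corr, inc)
  })
  res <- do.call(rbind, out)[, c("target_id", "model_id", "quality", "label")]
  rownames(res) <- NULL
  res
}

#' Benchmark-membership split (BM4 train / BM5-update validation)
#'
#' @param metadata data.frame `target_id`, `benchmark` with values `"BM4"`
#'   or `"BM5up"`.
#' @return list of class `dataset_split` with `scheme`, `train_targets`,
#'   `validation_targets`.
#' @export
split_bm4_bm5up <- function(metadata) {
  stopifnot(all(c("target_id", "benchmark") %in% names(metadata)))
  bad <- !(metadata$benchmark %in% c("BM4", "BM5up"))
  if (any(bad))
    stop("manifest error: untagged target(s): ",
         paste(metadata$target_id[bad], collapse = ", "))
  val <- metadata$target_id[metadata$benchmark == "BM5up"]
  if (length(val) == 0L) warning("empty validation set: no BM5up targets")
  structure(list(scheme = "bm4_vs_bm5up",
                 train_targets = metadata$target_id[metadata$benchmark == "BM4"],
                 validation_targets = val,
                 repeat_index = 1L, seed = NA_integer_),
            class = "dataset_split")
}

#' Repeated random target-level splits
#'
#' `repeats` independent seeded draws of `n_validation` validation targets
#' (64 in the reference protocol, with the remaining targets for training).
#'
#' @param targets character vector of target ids.
#' @param n_validation validation set size.
#' @param repeats number of independent splits.
#' @param seed integer seed.
#' @return list of `dataset_split` objects.
#' @export
repeated_random_splits <- function(targets, n_validation = 64, repeats = 10,
                                   seed = 1) {
  targets <- unique(targets)
  if (n_validation >= length(targets))
    stop("n_validation must be smaller than the number of targets")
  lapply(seq_len(repeats), function(r) {
    val <- .with_seed(as.integer((seed + 7919 * r) %% 2147483647),
                      sample(targets, n_validation))
    structure(list(scheme = "repeated_random",
                   train_targets = setdiff(targets, val),
                   validation_targets = val,
                   repeat_index = r, seed = seed),
              class = "dataset_split")
  })
}

#' @export
print.dataset_split <- function(x, ...) {
  cat(sprintf("<dataset_split %s #%d: %d train / %d validation targets>\n",
              x$scheme, x$repeat_index, length(x$train_targets),
              length(x$validation_targets)))
  invisible(x)
}
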