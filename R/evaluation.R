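# Evaluation: confusion counts, the standard binary metrics (precision,
# recall, accuracy, F1, Matthews correlation coefficient) reported for both
# classes, CAPRI-style top-N success rates with quality-tier breakdown, and
# mean +/- sd aggregation over repeated splits.

#' Confusion counts (positive class = correct)
#'
#' @param labels,predictions binary vectors (0 incorrect / 1 correct) of
#'   equal length.
#' @return list `Tp`, `Tn`, `Fp`, `Fn`.
#' @export
confusion <- function(labels, predictions) {
  if (length(labels) != length(predictions))
    stop("labels/predictions length mismatch")
  if (length(labels) < 1L) stop("empty vectors")
  labels <- as.integer(labels); predictions <- as.integer(predictions)
  list(Tp = sum(labels == 1L & predictions == 1L),
       Tn = sum(labels == 0L & predictions == 0L),
       Fp = sum(labels == 0L & predictions == 1L),
       Fn = sum(labels == 1L & predictions == 0L))
}

# Degenerate-case conventions: P or R with zero denominator -> 0 (flagged);
# F1 with P = R = 0 -> 0; MCC with any zero factor in the denominator -> 0.
.safe_div <- function(num, den) if (den == 0) 0 else num / den

#' Binary classification metrics for one class role
#'
#' Precision = Tp/(Tp+Fp); Recall = Tp/(Tp+Fn); Accuracy =
#' (Tp+Tn)/total; F1 = 2PR/(P+R); MCC = (Tp*Tn - Fp*Fn) /
#' sqrt((Tp+Fp)(Tp+Fn)(Tn+Fp)(Tn+Fn)). Per-class metrics for the
#' "incorrect" class are the same formulas with the class roles swapped.
#'
#' @param c confusion counts from [confusion()].
#' @return list with `P_corr`, `R_corr`, `F1_corr`, `P_inc`, `R_inc`,
#'   `F1_inc`, `Acc`, `MCC`, and `degenerate` (logical flag set when any
#'   precision/recall denominator was zero).
#' @export
metrics <- function(c) {
  with(c, {
    total <- Tp + Tn + Fp + Fn
    degenerate <- (Tp + Fp) == 0 || (Tp + Fn) == 0 ||
      (Tn + Fn) == 0 || (Tn + Fp) == 0
    P <- .safe_div(Tp, Tp + Fp); R <- .safe_div(Tp, Tp + Fn)
    Pi <- .safe_div(Tn, Tn + Fn); Ri <- .safe_div(Tn, Tn + Fp)
    f1 <- function(p, r) if (p + r == 0) 0 else 2 * p * r / (p + r)
    den2 <- as.numeric(Tp + Fp) * (Tp + Fn) * (Tn + Fp) * (Tn + Fn)
    mcc <- if (den2 == 0) 0 else
      (as.numeric(Tp) * Tn - as.numeric(Fp) * Fn) / sqrt(den2)
    list(P_corr = P, R_corr = R, F1_corr = f1(P, R),
         P_inc = Pi, R_inc = Ri, F1_inc = f1(Pi, Ri),
         Acc = .safe_div(Tp + Tn, total), MCC = mcc,
         degenerate = degenerate)
  })
}

#' Top-N success rate with quality-tier breakdown
#'
#' For each target, counts of acceptable-or-better, medium-or-better and
#' high-quality decoys among the N top-ranked ones; totals are the number of
#' targets with at least one hit in each tier. Targets with no correct decoy
#' available anywhere in their ranking are flagged unreachable.
#'
#' @param rankings named list: per target, an ordered character vector of
#'   model ids (best first).
#' @param qualities named list: per target, a named character vector mapping
#'   model id to quality label.
#' @param N ranking depth.
#' @return list with `per_target` (data.frame `target_id`, `acceptable_plus`,
#'   `medium_plus`, `high`, `reachable`) and `totals` (named counts of
#'   targets with >= 1 hit per tier, plus `n_targets`, `n_reachable`).
#' @export
success_rate <- function(rankings, qualities, N = 10) {
  if (N < 1) stop("N must be >= 1")
  stopifnot(all(names(rankings) %in% names(qualities)))
  rows <- lapply(names(rankings), function(t) {
    q_all <- qualities[[t]]
    top <- head(rankings[[t]], N)
    q <- q_all[top]
    data.frame(target_id = t,
               acceptable_plus = sum(q %in% c("acceptable", "medium", "high"),
                                     na.rm = TRUE),
               medium_plus = sum(q %in% c("medium", "high"), na.rm = TRUE),
               high = sum(q == "high", na.rm = TRUE),
               reachable = any(q_all %in% c("acceptable", "medium", "high")),
               stringsAsFactors = FALSE)
  })
  per_target <- do.call(rbind, rows)
  totals <- c(acceptable_plus = sum(per_target$acceptable_plus > 0),
              medium_plus = sum(per_target$medium_plus > 0),
              high = sum(per_target$high > 0),
              n_targets = nrow(per_target),
              n_reachable = sum(per_target$reachable))
  list(per_target = per_target, totals = totals, N = N)
}

#' Format a per-target success entry the conventional way
#'
#' `"9/3***/5**"` reads: 9 acceptable-or-better hits of which 3 high (***)
#' and 5 medium (**); zero-hit targets print `"0"`.
#'
#' @param acceptable_plus,medium_plus,high tier counts.
#' @return character.
#' @export
format_success <- function(acceptable_plus, medium_plus, high) {
  mapply(function(a, m, h) {
    if (a == 0) return("0")
    out <- as.character(a)
    if (h > 0) out <- paste0(out, "/", h, "***")
    if (m - h > 0) out <- paste0(out, "/", m - h, "**")
    out
  }, acceptable_plus, medium_plus, high)
}

#' Aggregate metric sets over repeated splits
#'
#' @param metric_sets list of [metrics()] results (>= 1).
#' @return data.frame `metric`, `mean`, `sd` (sample sd; `NA` for a single
#'   repeat).
#' @export
aggregate_over_repeats <- function(metric_sets) {
  stopifnot(length(metric_sets) >= 1L)
  keys <- c("P_corr", "R_corr", "F1_corr", "P_inc", "R_inc", "F1_inc",
            "Acc", "MCC")
  m <- sapply(keys, function(k)
    vapply(metric_sets, function(s) s[[k]], numeric(1)))
  m <- matrix(m, nrow = length(metric_sets),
              dimnames = list(NULL, keys))
  data.frame(metric = keys, mean = colMeans(m),
             sd = if (nrow(m) >= 2L) apply(m, 2, sd) else NA_real_,
             row.names = NULL)
}
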