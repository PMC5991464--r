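## Scoring of predicted per-drug preferred-term sets against gold
## annotations: per-drug recall/precision/F, with micro and macro
## aggregation across drugs.

#' Construct an evaluation result from raw counts
#'
#' @param tp true positives.
#' @param goldCount number of gold terms.
#' @param predictedCount number of predicted terms.
#' @return a list of class `EvaluationResult` with fields
#'   `true_positives`, `gold_count`, `predicted_count`, `recall`,
#'   `precision`, `f_score`. Recall is `tp/goldCount` (0 when the gold set
#'   is empty), precision `tp/predictedCount` (0 when nothing predicted),
#'   F the harmonic mean (0 when P + R = 0).
#' @export
evaluationResult <- function(tp, goldCount, predictedCount) {
  tp <- as.integer(tp); goldCount <- as.integer(goldCount)
  predictedCount <- as.integer(predictedCount)
  stopifnot(tp >= 0L, goldCount >= 0L, predictedCount >= 0L,
            tp <= goldCount, tp <= predictedCount)
  r <- if (goldCount > 0L) tp / goldCount else 0
  p <- if (predictedCount > 0L) tp / predictedCount else 0
  f <- if (p + r > 0) 2 * p * r / (p + r) else 0
  structure(list(true_positives = tp, gold_count = goldCount,
                 predicted_count = predictedCount,
                 recall = r, precision = p, f_score = f),
            class = "EvaluationResult")
}

#' @export
print.EvaluationResult <- function(x, ...) {
  cat(sprintf(
    "EvaluationResult: TP %d / gold %d / predicted %d  (R %.3f, P %.3f, F %.3f)\n",
    x$true_positives, x$gold_count, x$predicted_count,
    x$recall, x$precision, x$f_score))
  invisible(x)
}

#' Score one drug's predicted term set against gold
#'
#' Evaluation is at the level of normalized preferred terms: the true
#' positives are the set intersection of predicted and gold ids.
#'
#' @param predicted character vector of predicted term ids.
#' @param gold character vector of gold term ids.
#' @return an [evaluationResult()].
#' @export
evaluateDrug <- function(predicted, gold) {
  predicted <- unique(as.character(predicted))
  gold <- unique(as.character(gold))
  evaluationResult(length(intersect(predicted, gold)),
                   length(gold), length(predicted))
}

#' Aggregate per-drug evaluation results
#'
#' Micro-aggregation pools TP/gold/predicted counts over drugs and then
#' computes the metrics; macro-aggregation averages the per-drug metrics
#' (counts are still reported pooled). Reports should always state the
#' mode: the two generally differ.
#'
#' @param results nonempty list of [evaluationResult()] objects.
#' @param mode `"micro"` or `"macro"`.
#' @return an `EvaluationResult`.
#' @export
aggregateResults <- function(results, mode = c("micro", "macro")) {
  mode <- match.arg(mode)
  if (!length(results)) stop("cannot aggregate an empty result list")
  stopifnot(all(vapply(results, inherits, logical(1L), "EvaluationResult")))
  tp <- sum(vapply(results, `[[`, 0L, "true_positives"))
  g <- sum(vapply(results, `[[`, 0L, "gold_count"))
  p <- sum(vapply(results, `[[`, 0L, "predicted_count"))
  if (mode == "micro") return(evaluationResult(tp, g, p))
  out <- evaluationResult(tp, g, p)
  out$recall <- mean(vapply(results, `[[`, 0, "recall"))
  out$precision <- mean(vapply(results, `[[`, 0, "precision"))
  out$f_score <- mean(vapply(results, `[[`, 0, "f_score"))
  out
}
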