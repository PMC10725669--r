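#' Precision, recall, F-score and accuracy from a contingency table
#'
#' \eqn{P = TP/(TP+FP)}, \eqn{R = TP/(TP+FN)}, \eqn{F = 2PR/(P+R)},
#' \eqn{Acc = (TP+TN)/(TP+FP+FN+TN)}. Degenerate 0/0 ratios return 0 (with
#' a warning) so that empty classes do not poison macro averages; set
#' `degenerate = "nan"` to propagate `NaN` instead.
#'
#' @param TP,FP,FN,TN non-negative counts (total must be positive)
#' @param degenerate `"zero"` (default) or `"nan"`
#' @return named numeric vector `(P, R, F, Acc)`
#' @export
contingency_metrics <- function(TP, FP, FN, TN,
                                degenerate = c("zero", "nan")) {
  degenerate <- match.arg(degenerate)
  stopifnot(TP >= 0, FP >= 0, FN >= 0, TN >= 0)
  total <- TP + FP + FN + TN
  if (total == 0) stop("all-zero contingency table", call. = FALSE)
  safe_div <- function(num, den, what) {
    if (den == 0) {
      if (degenerate == "zero") {
        warning("degenerate ", what, " (0/0) reported as 0", call. = FALSE)
        return(0)
      }
      return(NaN)
    }
    num / den
  }
  P <- safe_div(TP, TP + FP, "precision")
  R <- safe_div(TP, TP + FN, "recall")
  F1 <- if (is.nan(P) || is.nan(R)) NaN
        else if (P + R == 0) 0 else 2 * P * R / (P + R)
  c(P = P, R = R, F = F1, Acc = (TP + TN) / total)
}

# one-vs-rest contingency counts of a single class
class_contingency <- function(pred, gold, cls) {
  list(TP = sum(pred == cls & gold == cls),
       FP = sum(pred == cls & gold != cls),
       FN = sum(pred != cls & gold == cls),
       TN = sum(pred != cls & gold != cls))
}

binary_contingency <- function(pred, gold, positive) {
  class_contingency(pred, gold, positive)
}

#' Per-class and averaged multi-class metrics
#'
#' Builds a one-vs-rest contingency table per class. The micro-averaged
#' F-score (CLA) comes from the global table summed over the included
#' classes; the macro-averaged F-score (MAVG) is the unweighted mean of
#' the per-class F-scores. An exclusion set (typically `"NEGATIVE"`, the
#' official challenge convention) removes classes from both averages while
#' still reporting their per-class rows.
#'
#' @param pred,gold character vectors of equal length
#' @param classes the full label set
#' @param exclude labels excluded from CLA/MAVG (default none)
#' @param degenerate see [contingency_metrics()]
#' @return list of class `metric_report`: `per_class` data frame
#'   (class, TP, FP, FN, TN, P, R, F), `accuracy`, `CLA`, `MAVG`,
#'   `micro` named vector (P, R, F)
#' @export
multiclass_report <- function(pred, gold, classes = sort(unique(c(pred, gold))),
                              exclude = NULL, degenerate = "zero") {
  if (length(pred) != length(gold))
    stop("pred and gold differ in length", call. = FALSE)
  bad <- setdiff(unique(c(pred, gold)), classes)
  if (length(bad))
    stop("labels outside the class set: ", paste(bad, collapse = ", "),
         call. = FALSE)
  rows <- lapply(classes, function(cls) {
    ct <- class_contingency(pred, gold, cls)
    m <- suppressWarnings(
      contingency_metrics(ct$TP, ct$FP, ct$FN, ct$TN,
                          degenerate = degenerate))
    data.frame(class = cls, TP = ct$TP, FP = ct$FP, FN = ct$FN, TN = ct$TN,
               P = m[["P"]], R = m[["R"]], F = m[["F"]],
               stringsAsFactors = FALSE)
  })
  per_class <- do.call(rbind, rows)
  included <- setdiff(classes, exclude)
  inc <- per_class[per_class$class %in% included, , drop = FALSE]
  micro_p <- sum(inc$TP) / max(sum(inc$TP) + sum(inc$FP), .Machine$double.eps)
  micro_r <- sum(inc$TP) / max(sum(inc$TP) + sum(inc$FN), .Machine$double.eps)
  cla <- if (micro_p + micro_r == 0) 0 else
    2 * micro_p * micro_r / (micro_p + micro_r)
  structure(list(per_class = per_class,
                 accuracy = mean(pred == gold),
                 CLA = cla, MAVG = mean(inc$F),
                 micro = c(P = micro_p, R = micro_r, F = cla),
                 included = included),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat("<metric_report>\n")
  print(x$per_class, row.names = FALSE)
  cat(sprintf("accuracy=%.4f  CLA=%.4f  MAVG=%.4f (averaged over: %s)\n",
              x$accuracy, x$CLA, x$MAVG, paste(x$included, collapse = ", ")))
  invisible(x)
}

#' Cross-corpus scalability score
#'
#' One minus the population standard deviation of a model's F-scores on
#' the two corpora: \eqn{1 - \sqrt{\tfrac12 (F_a - \mu)^2 + \tfrac12
#' (F_b - \mu)^2}} with \eqn{\mu} the mean, which for two values equals
#' \eqn{1 - |F_a - F_b| / 2}. A model that transfers well scores close
#' to 1.
#'
#' @param f_a,f_b F-scores in `[0, 1]` on the two corpora
#' @return scalar scalability score
#' @export
scalability_score <- function(f_a, f_b) {
  stopifnot(f_a >= 0, f_a <= 1, f_b >= 0, f_b <= 1)
  mu <- (f_a + f_b) / 2
  1 - sqrt(0.5 * (f_a - mu)^2 + 0.5 * (f_b - mu)^2)
}

#' Multi-run reproducibility summary
#'
#' Given per-epoch F-score traces of repeated training runs, computes the
#' population (divide-by-n) variance and standard deviation of F across
#' runs at each epoch, and returns their sums over epochs. Identical runs
#' give (0, 0); smaller sums mean a more reproducible training process.
#'
#' @param traces matrix (runs x epochs) or list of equal-length numeric
#'   vectors
#' @return list with `sum_variance`, `sum_std`, and the per-epoch vectors
#'   `variance`, `std`
#' @export
reproducibility_summary <- function(traces) {
  if (is.list(traces)) {
    lens <- lengths(traces)
    if (length(unique(lens)) != 1L)
      stop("runs have unequal epoch counts", call. = FALSE)
    traces <- do.call(rbind, traces)
  }
  if (nrow(traces) < 2L) stop("need at least 2 runs", call. = FALSE)
  n <- nrow(traces)
  mu <- colMeans(traces)
  v <- colMeans(traces^2) - mu^2         # population variance
  v[v < 0] <- 0                           # guard fp round-off
  s <- sqrt(v)
  list(sum_variance = sum(v), sum_std = sum(s), variance = v, std = s)
}

#' Welch's two-sample t-test
#'
#' Unequal-variance t statistic with Welch-Satterthwaite degrees of
#' freedom and a two-sided p-value; used to decide whether two models'
#' performance samples differ significantly. Degenerate inputs follow a
#' documented contract: two zero-variance samples with equal means give
#' `t = 0, p = 1`; with different means the difference is reported as
#' significant with `p = 0` (infinite evidence against equality).
#'
#' @param sample_a,sample_b numeric vectors, each of length >= 2
#' @param alpha significance level (default 0.05)
#' @return list with `t`, `df`, `p`, `significant`
#' @export
welch_t_test <- function(sample_a, sample_b, alpha = 0.05) {
  stopifnot(length(sample_a) >= 2L, length(sample_b) >= 2L)
  na <- length(sample_a); nb <- length(sample_b)
  va <- stats::var(sample_a); vb <- stats::var(sample_b)
  delta <- mean(sample_a) - mean(sample_b)
  if (va == 0 && vb == 0) {
    if (delta == 0)
      return(list(t = 0, df = na + nb - 2, p = 1, significant = FALSE))
    return(list(t = sign(delta) * Inf, df = na + nb - 2, p = 0,
                significant = TRUE))
  }
  se2 <- va / na + vb / nb
  t_stat <- delta / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * stats::pt(-abs(t_stat), df)
  list(t = t_stat, df = df, p = p, significant = p < alpha)
}

#' Score a predictions table against a gold corpus
#'
#' Joins a [predict_corpus()]-style table (or a TSV written by
#' [write_predictions()]) with the gold pair annotations of a corpus and
#' computes the task's metric report.
#'
#' @param corpus gold [ddi_corpus()]
#' @param predictions data frame with `sentence_id`, `e1`, `e2`, `label`
#' @param exclude labels to exclude from the averages (see
#'   [multiclass_report()])
#' @return a [multiclass_report()] object
#' @export
evaluate_predictions <- function(corpus, predictions, exclude = NULL) {
  gold_inst <- corpus_instances(corpus, gold = TRUE)
  key <- function(sid, e1, e2)
    paste(sid, pmin(e1, e2), pmax(e1, e2), sep = "\r")
  gold_map <- stats::setNames(
    vapply(gold_inst, `[[`, "", "label"),
    vapply(gold_inst, function(x) key(x$sentence$id, x$target1, x$target2), ""))
  pk <- key(predictions$sentence_id, predictions$e1, predictions$e2)
  hit <- pk %in% names(gold_map)
  if (!all(hit))
    stop("predictions reference unannotated pairs (first: ",
         predictions$sentence_id[!hit][1], ")", call. = FALSE)
  multiclass_report(predictions$label, unname(gold_map[pk]),
                    classes = task_labels(corpus$task), exclude = exclude)
}
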