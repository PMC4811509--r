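#' Per-assay classification metrics against outcome
#'
#' Treats the outcome event as the positive class and a methylated call as a
#' positive prediction, and computes per assay the sensitivity (TPR),
#' specificity (TNR) and balanced accuracy (BAC = (TPR + TNR) / 2) over
#' non-missing calls. An assay with no evaluable sample in one class gets 0
#' for the corresponding rate.
#'
#' @param calls ternary call matrix (samples x assays).
#' @param outcome logical event indicator per sample (both classes
#'   required).
#' @return data.frame with `assay_id`, `tpr`, `tnr`, `bac`.
#' @export
assay_metrics <- function(calls, outcome) {
  outcome <- as.logical(outcome)
  if (length(unique(outcome[!is.na(outcome)])) < 2L)
    stop("outcome must contain both classes")
  pos <- calls[outcome, , drop = FALSE]
  neg <- calls[!outcome, , drop = FALSE]
  tp <- colSums(pos == 1L, na.rm = TRUE)
  fn <- colSums(pos == 0L, na.rm = TRUE)
  tn <- colSums(neg == 0L, na.rm = TRUE)
  fp <- colSums(neg == 1L, na.rm = TRUE)
  tpr <- ifelse(tp + fn > 0, tp / (tp + fn), 0)
  tnr <- ifelse(tn + fp > 0, tn / (tn + fp), 0)
  data.frame(assay_id = colnames(calls), tpr = tpr, tnr = tnr,
             bac = (tpr + tnr) / 2, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Select the top assays at a percentile cutoff of a ranked metric
#'
#' Assays are ranked by the chosen metric from highest to lowest (ties
#' broken by assay id), and the top `ceiling(cutoff_pct/100 * n)` assays are
#' selected, with a minimum of one (a 0% cutoff selects the single best
#' assay).
#'
#' @param metrics data.frame from [assay_metrics()].
#' @param metric one of "TPR", "TNR", "BAC".
#' @param cutoff_pct percentile cutoff in \[0, 100\].
#' @return character vector of selected assay ids (in rank order).
#' @export
select_assays <- function(metrics, metric = c("BAC", "TPR", "TNR"),
                          cutoff_pct = 100) {
  metric <- match.arg(toupper(metric), c("BAC", "TPR", "TNR"))
  if (nrow(metrics) == 0L) stop("empty metric list")
  vals <- metrics[[tolower(metric)]]
  ord <- order(-vals, metrics$assay_id)
  k <- max(1L, ceiling(cutoff_pct / 100 * nrow(metrics)))
  metrics$assay_id[ord][seq_len(k)]
}

#' Risk prediction from a methylation score
#'
#' Samples with a methylation score strictly above the cutoff are predicted
#' methylation high-risk; at or below the cutoff, low-risk. `NA` scores give
#' `NA` predictions.
#'
#' @param score methylation score(s) in \[0, 100\].
#' @param score_cutoff_pct cutoff in \[0, 100\].
#' @return factor with levels `c("low", "high")`.
#' @export
predict_risk <- function(score, score_cutoff_pct) {
  factor(ifelse(score > score_cutoff_pct, "high", "low"),
         levels = c("low", "high"))
}

#' Enumerate the signature-candidate grid
#'
#' Full Cartesian product of ranking metric, assay-percentile cutoff and
#' methylation-score cutoff, in deterministic order (metric slowest, then
#' assay cutoff ascending, then score cutoff ascending). The defaults give
#' 3 x 21 x 21 = 1323 candidates.
#'
#' @param metrics character subset of `c("TPR", "TNR", "BAC")`.
#' @param assay_cutoffs percent grid for assay selection.
#' @param score_cutoffs percent grid for the methylation-score threshold.
#' @return data.frame with columns `metric`, `assay_cutoff_pct`,
#'   `score_cutoff_pct`.
#' @export
enumerate_candidates <- function(metrics = c("TPR", "TNR", "BAC"),
                                 assay_cutoffs = seq(0, 100, by = 5),
                                 score_cutoffs = seq(0, 100, by = 5)) {
  if (length(metrics) == 0L || length(assay_cutoffs) == 0L ||
      length(score_cutoffs) == 0L) stop("empty candidate grid")
  grid <- expand.grid(score_cutoff_pct = score_cutoffs,
                      assay_cutoff_pct = assay_cutoffs,
                      metric = metrics, stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  grid[, c("metric", "assay_cutoff_pct", "score_cutoff_pct")]
}

#' Jaccard similarity of two assay sets
#'
#' `|A intersect B| / |A union B|`; two empty sets are identical by
#' convention (similarity 1).
#'
#' @param set_a,set_b character vectors.
#' @return similarity in \[0, 1\].
#' @export
jaccard_index <- function(set_a, set_b) {
  u <- union(set_a, set_b)
  if (length(u) == 0L) return(1)
  length(intersect(set_a, set_b)) / length(u)
}

# BAC and event-percentage score of risk predictions vs outcome.
# event_pct_score = 1 - |fraction predicted high - fraction with event|.
evaluate_predictions <- function(pred_high, outcome) {
  ok <- !is.na(pred_high) & !is.na(outcome)
  pred_high <- pred_high[ok]; outcome <- outcome[ok]
  if (!length(pred_high)) stop("no evaluable samples")
  tp <- sum(pred_high & outcome); fn <- sum(!pred_high & outcome)
  tn <- sum(!pred_high & !outcome); fp <- sum(pred_high & !outcome)
  tpr <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  tnr <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  list(bac = (tpr + tnr) / 2,
       event_pct_score = 1 - abs(mean(pred_high) - mean(outcome)))
}

# Weighted harmonic mean with a hard zero rule: any non-positive component
# sends the combined value to 0.
combine_harmonic <- function(components, weights) {
  stopifnot(length(components) == length(weights), all(weights > 0))
  if (any(is.na(components)) || any(components <= 0)) return(0)
  sum(weights) / sum(weights / components)
}

# Draw B half-cohort subsamples (without replacement); redraw bounded times
# when a subcohort loses an outcome class. Caller controls the RNG state.
draw_subcohorts <- function(outcome, n_bootstrap, fraction = 0.5,
                            max_retry = 50L) {
  n <- length(outcome)
  k <- floor(fraction * n)
  if (k < 2L) stop("cohort too small for bootstrap subsampling")
  lapply(seq_len(n_bootstrap), function(b) {
    for (try in seq_len(max_retry)) {
      idx <- sample.int(n, k)
      if (length(unique(outcome[idx])) == 2L) return(idx)
    }
    warning("subcohort retained a single outcome class after ",
            max_retry, " redraws")
    idx
  })
}

#' Bootstrap robustness (mean Jaccard) of an assay-selection rule
#'
#' Repeatedly subsamples half of the cohort without replacement, reselects
#' the assay set with the same metric and cutoff, and averages the Jaccard
#' similarity between each subcohort's set and the full-cohort set.
#'
#' @param calls ternary call matrix.
#' @param outcome logical event indicator.
#' @param metric,assay_cutoff_pct the candidate's selection rule.
#' @param n_bootstrap number of subcohorts.
#' @param bootstrap_fraction fraction of samples per subcohort.
#' @param seed integer seed.
#' @return mean Jaccard similarity in \[0, 1\].
#' @export
bootstrap_robustness <- function(calls, outcome, metric, assay_cutoff_pct,
                                 n_bootstrap = 100L,
                                 bootstrap_fraction = 0.5, seed = 1L) {
  full_metrics <- assay_metrics(calls, outcome)
  full_set <- select_assays(full_metrics, metric, assay_cutoff_pct)
  with_seed(stage_seed(seed, "framework"), {
    subs <- draw_subcohorts(outcome, n_bootstrap, bootstrap_fraction)
    jac <- vapply(subs, function(idx) {
      sub_metrics <- assay_metrics(calls[idx, , drop = FALSE], outcome[idx])
      jaccard_index(select_assays(sub_metrics, metric, assay_cutoff_pct),
                    full_set)
    }, numeric(1))
    mean(jac)
  })
}
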