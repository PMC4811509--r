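#' Fit a multimarker methylation signature
#'
#' Runs the three-step signature-selection framework on a ternary MSP call
#' matrix and a binary outcome. Step 1 constructs candidate signatures over
#' the full grid of ranking metric (TPR, TNR or BAC), assay-percentile
#' cutoff and methylation-score cutoff (3 x 21 x 21 = 1323 candidates by
#' default). Step 2 evaluates each candidate's performance — balanced
#' accuracy of its risk predictions and a score for how closely the
#' predicted high-risk fraction matches the true event fraction — and its
#' robustness, the mean Jaccard similarity between the assay set reselected
#' on each of `n_bootstrap` half-cohort subsamples and the full-cohort set.
#' Step 3 combines the three values in a weighted harmonic mean (any zero
#' component zeroes the combination) and retains the candidate with the
#' highest combined value; ties go to the larger assay set, then the lower
#' score cutoff, then enumeration order.
#'
#' Samples whose methylation score is undefined for a candidate (all calls
#' missing within its assay set) are excluded from that candidate's
#' evaluation and counted in the returned object.
#'
#' @param calls ternary call matrix (samples x assays) in \{1, 0, NA\}.
#' @param outcome logical event indicator per sample (e.g. death of
#'   disease for overall survival).
#' @param metrics ranking metrics to scan.
#' @param assay_cutoffs,score_cutoffs percent grids.
#' @param n_bootstrap bootstrap subcohorts for the robustness step.
#' @param bootstrap_fraction subcohort fraction of the cohort.
#' @param weights positive weights for (BAC, event-percentage score, mean
#'   Jaccard) in the harmonic mean.
#' @param seed integer seed controlling the bootstrap draws.
#' @return an object of class `meth_signature` with components
#'   `assay_set`, `metric`, `assay_cutoff_pct`, `score_cutoff_pct`,
#'   `evaluation` (bac, event_pct_score, mean_jaccard, combined), the full
#'   candidate `grid`, and the training `assay_metrics`.
#' @seealso [predict.meth_signature()], [train_and_validate()]
#' @examples
#' cfg <- sim_config(n_patients = 60, seed = 42)
#' cohort <- simulate_cohort(cfg)
#' sim <- simulate_calls(cohort, cfg)
#' fit <- meth_signature(sim$calls, cohort$os_event,
#'                       n_bootstrap = 20, seed = 42)
#' fit
#' @export
meth_signature <- function(calls, outcome,
                           metrics = c("TPR", "TNR", "BAC"),
                           assay_cutoffs = seq(0, 100, by = 5),
                           score_cutoffs = seq(0, 100, by = 5),
                           n_bootstrap = 100L, bootstrap_fraction = 0.5,
                           weights = c(bac = 1, event_pct = 1, jaccard = 1),
                           seed = 1L) {
  outcome <- as.logical(outcome)
  stopifnot(is.matrix(calls), nrow(calls) == length(outcome))
  if (length(unique(outcome)) < 2L) stop("outcome must contain both classes")
  if (length(weights) != 3L || any(weights <= 0))
    stop("weights must be three positive values")
  grid <- enumerate_candidates(metrics, assay_cutoffs, score_cutoffs)
  full_metrics <- assay_metrics(calls, outcome)

  # assay sets, per-sample scores and bootstrap Jaccard depend only on
  # (metric, assay cutoff); compute once per selection rule
  rules <- unique(grid[, c("metric", "assay_cutoff_pct")])
  rule_key <- function(m, c) paste(m, c, sep = "@")
  sets <- list(); scores <- list()
  for (i in seq_len(nrow(rules))) {
    set_i <- select_assays(full_metrics, rules$metric[i],
                           rules$assay_cutoff_pct[i])
    key <- rule_key(rules$metric[i], rules$assay_cutoff_pct[i])
    sets[[key]] <- set_i
    scores[[key]] <- methylation_score(calls, set_i)
  }

  mean_jac <- with_seed(stage_seed(seed, "framework"), {
    subs <- draw_subcohorts(outcome, n_bootstrap, bootstrap_fraction)
    sub_metrics <- lapply(subs, function(idx)
      assay_metrics(calls[idx, , drop = FALSE], outcome[idx]))
    vapply(seq_len(nrow(rules)), function(i) {
      key <- rule_key(rules$metric[i], rules$assay_cutoff_pct[i])
      mean(vapply(sub_metrics, function(sm)
        jaccard_index(select_assays(sm, rules$metric[i],
                                    rules$assay_cutoff_pct[i]),
                      sets[[key]]), numeric(1)))
    }, numeric(1))
  })
  names(mean_jac) <- rule_key(rules$metric, rules$assay_cutoff_pct)

  grid$n_assays <- NA_integer_
  grid$bac <- grid$event_pct_score <- grid$mean_jaccard <-
    grid$combined <- NA_real_
  n_score_na <- 0L
  for (i in seq_len(nrow(grid))) {
    key <- rule_key(grid$metric[i], grid$assay_cutoff_pct[i])
    sc <- scores[[key]]
    pred <- sc > grid$score_cutoff_pct[i]
    ev <- evaluate_predictions(pred, outcome)
    grid$n_assays[i] <- length(sets[[key]])
    grid$bac[i] <- ev$bac
    grid$event_pct_score[i] <- ev$event_pct_score
    grid$mean_jaccard[i] <- mean_jac[[key]]
    grid$combined[i] <- combine_harmonic(
      c(ev$bac, ev$event_pct_score, mean_jac[[key]]), weights)
  }
  n_score_na <- sum(vapply(scores, function(s) sum(is.na(s)), numeric(1)))

  ord <- order(-grid$combined, -grid$n_assays, grid$score_cutoff_pct,
               seq_len(nrow(grid)))
  best <- grid[ord[1], ]
  best_key <- rule_key(best$metric, best$assay_cutoff_pct)
  structure(list(
    assay_set = sets[[best_key]],
    metric = best$metric,
    assay_cutoff_pct = best$assay_cutoff_pct,
    score_cutoff_pct = best$score_cutoff_pct,
    evaluation = list(bac = best$bac,
                      event_pct_score = best$event_pct_score,
                      mean_jaccard = best$mean_jaccard,
                      combined = best$combined),
    grid = grid,
    assay_metrics = full_metrics,
    weights = weights,
    n_bootstrap = n_bootstrap,
    bootstrap_fraction = bootstrap_fraction,
    n_samples = nrow(calls),
    n_undefined_scores = n_score_na,
    seed = seed,
    call = match.call()
  ), class = "meth_signature")
}

#' @export
print.meth_signature <- function(x, ...) {
  cat("Multimarker methylation signature\n")
  cat(sprintf("  %d assays selected by %s at the %g%% percentile cutoff\n",
              length(x$assay_set), x$metric, x$assay_cutoff_pct))
  cat(sprintf("  methylation score cutoff: %g%% (score > cutoff => high risk)\n",
              x$score_cutoff_pct))
  ev <- x$evaluation
  cat(sprintf("  training BAC %.3f | event-%% score %.3f | mean Jaccard %.3f | combined %.3f\n",
              ev$bac, ev$event_pct_score, ev$mean_jaccard, ev$combined))
  cat(sprintf("  grid: %d candidates, %d bootstraps, seed %d\n",
              nrow(x$grid), x$n_bootstrap, x$seed))
  invisible(x)
}

#' @method summary meth_signature
#' @export
summary.meth_signature <- function(object, n_top = 5L, ...) {
  g <- object$grid
  top <- g[order(-g$combined)[seq_len(min(n_top, nrow(g)))], ]
  structure(list(fit = object, top_candidates = top),
            class = "summary.meth_signature")
}

#' @export
print.summary.meth_signature <- function(x, ...) {
  print(x$fit)
  cat("\nTop candidates by combined harmonic mean:\n")
  print(x$top_candidates, row.names = FALSE, digits = 4)
  cat("\nSelected assays:\n")
  cat(strwrap(paste(x$fit$assay_set, collapse = ", "), width = 76,
              prefix = "  "), sep = "\n")
  invisible(x)
}

#' @method coef meth_signature
#' @export
coef.meth_signature <- function(object, ...) {
  m <- object$assay_metrics
  setNames(m[[tolower(object$metric)]], m$assay_id)[object$assay_set]
}

#' Predict methylation risk for new samples
#'
#' Applies the frozen signature (assay set and score cutoff) to a new call
#' matrix over the same assay universe.
#'
#' @param object a fitted [meth_signature()].
#' @param newdata ternary call matrix (samples x assays).
#' @param type "class" for risk classes, "score" for methylation scores,
#'   "both" for a data.frame with both.
#' @param ... unused.
#' @return per `type`: a factor, a numeric vector, or a data.frame with
#'   `sample_id`, `score`, `risk`.
#' @export
predict.meth_signature <- function(object, newdata,
                                   type = c("class", "score", "both"),
                                   ...) {
  type <- match.arg(type)
  if (!all(object$assay_set %in% colnames(newdata)))
    stop("assay universe mismatch: signature assays absent from newdata")
  score <- methylation_score(newdata, object$assay_set)
  risk <- predict_risk(score, object$score_cutoff_pct)
  switch(type,
         score = score,
         class = risk,
         both = data.frame(sample_id = rownames(newdata), score = score,
                           risk = risk, row.names = NULL,
                           stringsAsFactors = FALSE))
}

#' Plot the candidate grid of a fitted signature
#'
#' Shows the combined harmonic-mean value over the assay-cutoff x
#' score-cutoff grid for the selected metric, with the chosen candidate
#' marked.
#'
#' @param x a fitted [meth_signature()].
#' @param ... passed to [graphics::image()].
#' @method plot meth_signature
#' @export
plot.meth_signature <- function(x, ...) {
  g <- x$grid[x$grid$metric == x$metric, ]
  ac <- sort(unique(g$assay_cutoff_pct))
  sc <- sort(unique(g$score_cutoff_pct))
  z <- matrix(NA_real_, length(ac), length(sc))
  z[cbind(match(g$assay_cutoff_pct, ac), match(g$score_cutoff_pct, sc))] <-
    g$combined
  graphics::image(ac, sc, z, xlab = "assay cutoff (%)",
                  ylab = "score cutoff (%)",
                  main = sprintf("Combined value (%s ranking)", x$metric),
                  ...)
  graphics::points(x$assay_cutoff_pct, x$score_cutoff_pct, pch = 4,
                   cex = 2, lwd = 2)
  invisible(x)
}

#' Train a signature on one cohort and validate it on another
#'
#' Runs the framework end-to-end on the training cohort only, then applies
#' the frozen assay set and score cutoff unchanged to the validation
#' cohort. No information flows from validation to training.
#'
#' @param train_calls,train_outcome training cohort call matrix and event
#'   indicator.
#' @param valid_calls,valid_outcome validation cohort.
#' @param ... passed to [meth_signature()].
#' @return list of class `meth_signature_validation` with the `fit`,
#'   per-cohort `predictions` and `evaluation` (bac, event_pct_score).
#' @export
train_and_validate <- function(train_calls, train_outcome,
                               valid_calls, valid_outcome, ...) {
  if (!identical(colnames(train_calls), colnames(valid_calls)))
    stop("assay universe mismatch between cohorts")
  fit <- meth_signature(train_calls, train_outcome, ...)
  pred_train <- predict(fit, train_calls, type = "both")
  pred_valid <- predict(fit, valid_calls, type = "both")
  structure(list(
    fit = fit,
    predictions = list(train = pred_train, validation = pred_valid),
    evaluation = list(
      train = evaluate_predictions(pred_train$risk == "high",
                                   as.logical(train_outcome)),
      validation = evaluate_predictions(pred_valid$risk == "high",
                                        as.logical(valid_outcome)))
  ), class = "meth_signature_validation")
}

#' @export
print.meth_signature_validation <- function(x, ...) {
  print(x$fit)
  cat(sprintf("\n  validation BAC %.3f | event-%% score %.3f (n = %d)\n",
              x$evaluation$validation$bac,
              x$evaluation$validation$event_pct_score,
              nrow(x$predictions$validation)))
  invisible(x)
}
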