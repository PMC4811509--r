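#' Kaplan-Meier estimate with Greenwood log-log confidence intervals
#'
#' Product-limit estimator of the survivor function with 95% confidence
#' intervals from the Greenwood variance on the log(-log S) scale.
#'
#' @param time non-negative follow-up times (days).
#' @param event logical event indicator (TRUE = event observed).
#' @return object of class `km_curve`: a data.frame `table` with `time`,
#'   `n_risk`, `n_event`, `survival`, `std_err`, `ci_lower`, `ci_upper`,
#'   plus the underlying [survival::survfit] object.
#' @export
km_estimate <- function(time, event) {
  if (any(time < 0) || any(!is.finite(time))) stop("times must be finite and >= 0")
  fit <- survival::survfit(survival::Surv(time, as.integer(event)) ~ 1,
                           conf.type = "log-log", conf.int = 0.95)
  tab <- data.frame(time = fit$time, n_risk = fit$n.risk,
                    n_event = fit$n.event, survival = fit$surv,
                    std_err = fit$std.err,
                    ci_lower = fit$lower, ci_upper = fit$upper)
  structure(list(table = tab, fit = fit, n = length(time),
                 n_events = sum(event)), class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("Kaplan-Meier curve: %d samples, %d events\n", x$n,
              x$n_events))
  print(head(x$table, 10), row.names = FALSE, digits = 4)
  if (nrow(x$table) > 10) cat("  ...\n")
  invisible(x)
}

#' Survival probability (and CI) at given times
#'
#' Right-continuous step lookup of a Kaplan-Meier curve.
#'
#' @param km a [km_estimate()] result.
#' @param times query times.
#' @return data.frame with `time`, `survival`, `ci_lower`, `ci_upper`.
#' @export
km_survival_at <- function(km, times) {
  s <- summary(km$fit, times = times, extend = TRUE)
  data.frame(time = s$time, survival = s$surv,
             ci_lower = s$lower, ci_upper = s$upper)
}

#' Two-group log-rank test
#'
#' Standard observed-minus-expected statistic with hypergeometric variance,
#' referred to chi-square with one degree of freedom.
#'
#' @param time,event follow-up times and event indicators.
#' @param group two-level group labels.
#' @return list with `chi_square`, `p_value`, `observed`, `expected`.
#' @export
logrank_test <- function(time, event, group) {
  group <- as.factor(group)
  if (nlevels(droplevels(group)) != 2L) stop("exactly two non-empty groups required")
  if (sum(event) == 0L) stop("log-rank test undefined with zero events")
  sd <- survival::survdiff(survival::Surv(time, as.integer(event)) ~ group)
  p <- pchisq(sd$chisq, df = 1, lower.tail = FALSE)
  list(chi_square = unname(sd$chisq), p_value = max(p, .Machine$double.xmin),
       observed = sd$obs, expected = sd$exp)
}

#' Logistic regression with odds ratios and Wald confidence intervals
#'
#' Maximum-likelihood logistic fit (univariable or multivariable) reporting
#' per-predictor coefficients, odds ratios and 95% Wald intervals
#' `exp(coef +/- 1.96 SE)`. Reference levels are whatever is coded 0/first
#' in the supplied design.
#'
#' @param response logical/binary outcome.
#' @param predictors data.frame of predictors (binary predictors coded with
#'   the reference level as 0 or first factor level).
#' @return data.frame with `term`, `coefficient`, `odds_ratio`, `ci95_low`,
#'   `ci95_high`, `p_value` (intercept excluded).
#' @export
logistic_fit <- function(response, predictors) {
  response <- as.logical(response)
  if (length(unique(response)) < 2L) stop("response must contain both classes")
  df <- data.frame(.y = response, predictors, check.names = FALSE)
  fit <- withCallingHandlers(
    glm(.y ~ ., data = df, family = binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        stop("complete separation: logistic fit did not converge", call. = FALSE)
      invokeRestart("muffleWarning")
    })
  cf <- coef(fit)
  if (anyNA(cf)) stop("singular design: collinear or constant predictor")
  eps <- 1e-8
  if (!fit$converged || any(fit$fitted.values < eps) ||
      any(fit$fitted.values > 1 - eps))
    stop("complete separation: logistic fit did not converge")
  se <- sqrt(diag(vcov(fit)))
  z <- cf / se
  keep <- names(cf) != "(Intercept)"
  data.frame(term = names(cf)[keep],
             coefficient = unname(cf[keep]),
             odds_ratio = unname(exp(cf[keep])),
             ci95_low = unname(exp(cf[keep] - 1.96 * se[keep])),
             ci95_high = unname(exp(cf[keep] + 1.96 * se[keep])),
             p_value = unname(2 * pnorm(-abs(z[keep]))),
             stringsAsFactors = FALSE)
}

#' Fisher's exact test for r x c contingency tables
#'
#' Two-sided exact test. For 2 x 2 tables the p-value is the sum of
#' hypergeometric probabilities of all tables (with fixed margins) whose
#' probability does not exceed that of the observed table; small r x c
#' tables (r*c <= 16) use the exact Freeman-Halton network algorithm;
#' larger tables fall back to seeded Monte-Carlo with at least 1e5
#' simulated tables.
#'
#' @param table non-negative integer matrix.
#' @param mc_tables Monte-Carlo sample size for large tables.
#' @param seed seed for the Monte-Carlo fallback.
#' @return list with `p_value`, `method`, and for Monte-Carlo results the
#'   standard error `mc_se`.
#' @export
fisher_exact <- function(table, mc_tables = 1e5, seed = 1L) {
  table <- as.matrix(table)
  if (any(table < 0) || any(table != round(table)))
    stop("cells must be non-negative integers")
  if (prod(dim(table)) <= 16L) {
    list(p_value = fisher.test(table)$p.value, method = "exact")
  } else {
    p <- with_seed(seed,
      fisher.test(table, simulate.p.value = TRUE, B = mc_tables)$p.value)
    list(p_value = p, method = "monte-carlo",
         mc_se = sqrt(p * (1 - p) / mc_tables))
  }
}

#' Power of the two-sided log-rank test (Freedman approximation)
#'
#' The hazard ratio is derived from the two groups' survival probabilities
#' at the study horizon under proportional hazards
#' (`HR = log(surv_high) / log(surv_low)`), the expected event count from
#' the per-group event probabilities, and the power from the Freedman
#' normal approximation with allocation ratio `n_high / n_low`:
#' `power = Phi(delta - z) + Phi(-delta - z)` with
#' `delta = |HR - 1| * sqrt(d * phi) / (1 + phi * HR)`.
#'
#' @param surv_low survival probability at the horizon in the good-outcome
#'   group, in (0, 1).
#' @param surv_high survival probability in the poor-outcome group.
#' @param n_low,n_high group sizes.
#' @param alpha two-sided significance level.
#' @return power in \[0, 1\] (equal survival gives power = alpha, the size
#'   of the test).
#' @export
logrank_power <- function(surv_low, surv_high, n_low, n_high,
                          alpha = 0.05) {
  if (!is_prob(surv_low) || !is_prob(surv_high) ||
      surv_low <= 0 || surv_low >= 1 || surv_high <= 0 || surv_high >= 1)
    stop("survival probabilities must lie strictly in (0, 1)")
  if (!is_prob(alpha) || alpha <= 0 || alpha >= 1)
    stop("alpha must lie in (0, 1)")
  hr <- log(surv_high) / log(surv_low)
  d <- n_low * (1 - surv_low) + n_high * (1 - surv_high)
  phi <- n_high / n_low
  z <- qnorm(1 - alpha / 2)
  delta <- abs(hr - 1) * sqrt(d * phi) / (1 + phi * hr)
  pnorm(delta - z) + pnorm(-delta - z)
}
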