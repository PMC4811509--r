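#' Median-of-ratios size factors
#'
#' Per-sample normalisation scalars for region count matrices: the factor of
#' a sample is the median, over regions whose geometric mean across samples
#' is positive, of the ratio of the sample's count to that geometric mean.
#' Normalised counts are `count / factor`.
#'
#' @param counts integer matrix, regions x samples.
#' @return positive numeric vector of per-sample size factors.
#' @export
size_factors <- function(counts) {
  if (any(colSums(counts) == 0)) stop("sample with all-zero counts")
  log_geo <- rowMeans(log(counts))          # -Inf where any count is zero
  use <- is.finite(log_geo)
  if (!any(use)) stop("no region with positive counts in every sample")
  sf <- apply(counts[use, , drop = FALSE], 2, function(col)
    exp(median(log(col) - log_geo[use])))
  if (any(!is.finite(sf) | sf <= 0)) stop("degenerate size factors")
  sf
}

#' Simplified negative-binomial differential test for region counts
#'
#' A reduced-fidelity two-group test on normalised counts: per-sample counts
#' are divided by median-of-ratios size factors, the log2 fold change is
#' computed on pseudocounted group means, and group means are compared by a
#' Wald-type statistic whose variance comes from a negative-binomial
#' mean-variance relation (`var = mu + phi * mu^2`) with a single pooled
#' method-of-moments dispersion `phi` (floored at 0, i.e. Poisson at the
#' boundary), referred to a t distribution with `nA + nB - 2` degrees of
#' freedom.
#'
#' @param counts integer matrix, regions x samples.
#' @param group_labels vector of "A"/"B" per sample (group B is the
#'   poor-outcome group; positive fold changes mean higher counts in B).
#' @param pseudocount added to both group means in the fold change.
#' @param sf optional precomputed size factors.
#' @return data.frame with `region_id`, `mean_norm_a`, `mean_norm_b`,
#'   `log2_fold_change`, `p_value` (always in (0, 1]).
#' @export
differential_test <- function(counts, group_labels, pseudocount = 0.5,
                              sf = NULL) {
  if (length(unique(group_labels)) < 2L)
    stop("both groups must be non-empty")
  if (is.null(sf)) sf <- size_factors(counts)
  norm <- sweep(counts, 2, sf, "/")
  a <- group_labels == "A"
  b <- group_labels == "B"
  na <- sum(a); nb <- sum(b)
  mean_a <- rowMeans(norm[, a, drop = FALSE])
  mean_b <- rowMeans(norm[, b, drop = FALSE])
  var_a <- apply(norm[, a, drop = FALSE], 1, stats::var)
  var_b <- apply(norm[, b, drop = FALSE], 1, stats::var)
  # pooled method-of-moments NB dispersion across regions, floored at 0
  phi_region <- ((var_a * (na - 1) + var_b * (nb - 1)) / (na + nb - 2) -
                   (mean_a + mean_b) / 2) / ((mean_a + mean_b) / 2)^2
  phi <- max(0, median(phi_region, na.rm = TRUE))
  v_a <- mean_a + phi * mean_a^2
  v_b <- mean_b + phi * mean_b^2
  se <- sqrt(v_a / na + v_b / nb)
  stat <- ifelse(se > 0, (mean_b - mean_a) / se, 0)
  p <- 2 * pt(-abs(stat), df = na + nb - 2)
  p <- pmin(1, pmax(p, .Machine$double.xmin))
  data.frame(region_id = rownames(counts),
             mean_norm_a = mean_a, mean_norm_b = mean_b,
             log2_fold_change = log2((mean_b + pseudocount) /
                                       (mean_a + pseudocount)),
             p_value = p, row.names = NULL, stringsAsFactors = FALSE)
}

#' The pi significance score for ranking DMRs
#'
#' `pi = -ln(p) * log2 fold change`; large positive values flag regions that
#' are both strongly significant and hypermethylated in the comparison
#' group. The sign always equals the sign of the fold change.
#'
#' @param p_value p-value(s) in (0, 1].
#' @param log2_fold_change log2 fold change(s).
#' @return numeric pi score(s).
#' @export
pi_score <- function(p_value, log2_fold_change) {
  if (any(p_value <= 0 | p_value > 1)) stop("p_value must lie in (0, 1]")
  -log(p_value) * log2_fold_change
}

#' Rank candidate DMRs by pi score with input-background exclusion
#'
#' The same differential test run on the matched input (non-enriched) data
#' estimates the background signal: a region whose input-data test is itself
#' significant (p below `background_alpha`) with a fold change in the same
#' direction as the enriched result is flagged as a background artifact and
#' excluded. Remaining regions hypermethylated in the poor-outcome group
#' (positive fold change) are ranked by pi score, descending, ties broken by
#' region id.
#'
#' @param enriched_results data.frame from [differential_test()] on the
#'   MBD-enriched counts.
#' @param input_results matching data.frame from the input counts.
#' @param top_k number of regions to return.
#' @param background_alpha significance level of the input-background test.
#' @return data.frame of the top regions with `pi_score`,
#'   `background_flagged` and `rank` columns (flagged regions excluded).
#' @export
rank_dmrs <- function(enriched_results, input_results, top_k = 20L,
                      background_alpha = 0.05) {
  if (!identical(sort(enriched_results$region_id),
                 sort(input_results$region_id)))
    stop("enriched and input results must share region ids")
  inp <- input_results[match(enriched_results$region_id,
                             input_results$region_id), ]
  res <- enriched_results
  res$pi_score <- pi_score(res$p_value, res$log2_fold_change)
  res$background_flagged <- inp$p_value < background_alpha &
    sign(inp$log2_fold_change) == sign(res$log2_fold_change) &
    inp$log2_fold_change != 0
  keep <- !res$background_flagged & res$log2_fold_change > 0
  ranked <- res[keep, , drop = FALSE]
  ord <- order(-ranked$pi_score, ranked$region_id)
  ranked <- ranked[ord, , drop = FALSE]
  ranked <- head(ranked, top_k)
  if (nrow(ranked)) ranked$rank <- seq_len(nrow(ranked))
  else ranked$rank <- integer(0)
  rownames(ranked) <- NULL
  ranked
}
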