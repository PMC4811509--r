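#' Thresholds for MSP methylation calling
#'
#' Tolerances applied when comparing a test amplification to the positive
#' (fully methylated) control: maximum Cq delay in cycles, maximum melting
#' temperature deviation in degrees C, amplicon size tolerance in bp, and
#' minimum melt-peak height as a fraction of the control's peak height.
#' These defaults are plausible qPCR tolerances; tune them to the assay
#' chemistry at hand.
#'
#' @param delta_cq_max maximum Cq above the positive control (cycles).
#' @param delta_tm_max maximum absolute Tm deviation (degrees C).
#' @param size_tol_bp amplicon size tolerance (bp).
#' @param min_height_frac minimum peak height as a fraction of the control.
#' @return list of class `calling_thresholds`.
#' @export
calling_thresholds <- function(delta_cq_max = 2, delta_tm_max = 1,
                               size_tol_bp = 5L, min_height_frac = 0.1) {
  if (any(c(delta_cq_max, delta_tm_max, size_tol_bp, min_height_frac) < 0))
    stop("all tolerances must be >= 0")
  structure(list(delta_cq_max = delta_cq_max, delta_tm_max = delta_tm_max,
                 size_tol_bp = size_tol_bp,
                 min_height_frac = min_height_frac),
            class = "calling_thresholds")
}

check_positive_control <- function(pos) {
  if (is.na(pos$cq) || is.na(pos$tm) || is.na(pos$size_bp) ||
      is.na(pos$peak_height))
    stop("positive control without complete amplification data: invalid run")
}

#' Call methylation status of one measurement against the positive control
#'
#' A measurement is called methylated only if it amplifies (Cq present) no
#' later than `delta_cq_max` cycles after the positive control, with melting
#' temperature within `delta_tm_max`, amplicon size within `size_tol_bp`,
#' and melt-peak height at least `min_height_frac` of the control's. Absent
#' amplification or a clean failure of any criterion yields unmethylated
#' (0). A measurement that amplifies but cannot be evaluated (missing Tm,
#' size or height) yields `NA`.
#'
#' @param m one-row data.frame or list with `cq`, `tm`, `size_bp`,
#'   `peak_height` (`NA` = absent).
#' @param pos the positive-control measurement for the same assay.
#' @param thr a [calling_thresholds()].
#' @param check_tm set `FALSE` for CpG-free control assays where Tm carries
#'   no methylation information.
#' @return integer: 1 (methylated), 0 (unmethylated) or `NA` (missing).
#' @export
call_assay <- function(m, pos, thr = calling_thresholds(),
                       check_tm = TRUE) {
  check_positive_control(pos)
  if (is.na(m$cq)) return(0L)                     # no amplification
  if (m$cq > pos$cq + thr$delta_cq_max) return(0L)  # clean Cq failure
  crit <- c(
    tm = if (check_tm) abs(m$tm - pos$tm) <= thr$delta_tm_max else TRUE,
    size = abs(m$size_bp - pos$size_bp) <= thr$size_tol_bp,
    height = m$peak_height >= thr$min_height_frac * pos$peak_height)
  if (any(is.na(crit))) return(NA_integer_)       # unevaluable
  if (all(crit)) 1L else 0L
}

#' Build a ternary call matrix from raw MSP measurements
#'
#' Applies [call_assay()] to every (sample, assay) measurement against the
#' per-assay positive control.
#'
#' @param measurements data.frame with columns `sample_id`, `assay_id`,
#'   `cq`, `tm`, `size_bp`, `peak_height` (`NA` = absent).
#' @param positive_controls data.frame with one row per assay (same
#'   measurement columns).
#' @param thr a [calling_thresholds()].
#' @return integer matrix samples x assays in \{1, 0, NA\}; pairs never
#'   measured are `NA`.
#' @export
build_call_matrix <- function(measurements, positive_controls,
                              thr = calling_thresholds()) {
  samples <- unique(as.character(measurements$sample_id))
  assays <- unique(as.character(measurements$assay_id))
  pos_idx <- match(assays, positive_controls$assay_id)
  if (anyNA(pos_idx)) stop("missing positive control for some assays")
  calls <- matrix(NA_integer_, length(samples), length(assays),
                  dimnames = list(samples, assays))
  for (i in seq_len(nrow(measurements))) {
    row <- measurements[i, ]
    pos <- positive_controls[pos_idx[match(row$assay_id, assays)], ]
    calls[as.character(row$sample_id), as.character(row$assay_id)] <-
      call_assay(row, pos, thr)
  }
  calls
}

#' ACTB sample quality control
#'
#' The ACTB control assay contains no CpG sites, so it must amplify in every
#' sample with adequate DNA preparation. A sample fails QC when its ACTB
#' amplification fails the calling criteria against the ACTB positive
#' control (Cq, size and height; Tm is ignored for the CpG-free assay).
#' Failing samples are removed from the call matrix.
#'
#' @param calls ternary call matrix (samples x assays).
#' @param actb_measurements data.frame of ACTB measurements, one row per
#'   sample (`sample_id`, `cq`, `tm`, `size_bp`, `peak_height`).
#' @param actb_pos the ACTB positive-control measurement.
#' @param thr a [calling_thresholds()].
#' @return list with `calls` (filtered matrix), `actb_pass` (named logical
#'   per sample) and `n_removed`.
#' @export
actb_qc <- function(calls, actb_measurements, actb_pos,
                    thr = calling_thresholds()) {
  samples <- rownames(calls)
  idx <- match(samples, actb_measurements$sample_id)
  if (anyNA(idx)) stop("missing ACTB measurement for some samples")
  pass <- vapply(idx, function(i) {
    cl <- call_assay(actb_measurements[i, ], actb_pos, thr, check_tm = FALSE)
    !is.na(cl) && cl == 1L
  }, logical(1))
  names(pass) <- samples
  list(calls = calls[pass, , drop = FALSE], actb_pass = pass,
       n_removed = sum(!pass))
}

#' Per-sample methylation score
#'
#' The percentage of methylated assays among the non-missing calls of the
#' given assay set: `100 * n_methylated / n_non_missing`. Samples whose
#' calls are all missing within the set get `NA` (flagged, excluded
#' downstream).
#'
#' @param calls ternary call matrix (samples x assays) or a single sample's
#'   call vector.
#' @param assay_set character vector of assay ids (defaults to all assays).
#' @return numeric vector of scores in \[0, 100\] (named by sample for a
#'   matrix input).
#' @export
methylation_score <- function(calls, assay_set = NULL) {
  if (is.null(dim(calls))) calls <- matrix(calls, nrow = 1,
                                           dimnames = list("sample",
                                                           names(calls)))
  if (is.null(assay_set)) assay_set <- colnames(calls)
  if (length(assay_set) == 0L) stop("assay_set must be non-empty")
  if (!all(assay_set %in% colnames(calls)))
    stop("unknown assay ids in assay_set")
  sub <- calls[, assay_set, drop = FALSE]
  n_meth <- rowSums(sub == 1L, na.rm = TRUE)
  n_eval <- rowSums(!is.na(sub))
  score <- ifelse(n_eval > 0, 100 * n_meth / n_eval, NA_real_)
  names(score) <- rownames(calls)
  score
}

#' Compare per-sample methylation burden between two groups
#'
#' Counts methylation events (methylated calls) per sample and compares the
#' two groups with a two-sided Wilcoxon rank-sum test.
#'
#' @param calls ternary call matrix (samples x assays).
#' @param group_labels two-level vector per sample.
#' @return list with `group_means` (named), `p_value` and the per-sample
#'   `counts`.
#' @export
methylation_burden_compare <- function(calls, group_labels) {
  groups <- unique(as.character(group_labels))
  if (length(groups) != 2L) stop("exactly two non-empty groups required")
  counts <- rowSums(calls == 1L, na.rm = TRUE)
  g <- as.character(group_labels)
  means <- tapply(counts, g, mean)
  p <- wilcox.test(counts[g == groups[1]], counts[g == groups[2]],
                   exact = FALSE)$p.value
  if (is.na(p)) p <- 1     # fully tied samples carry no evidence
  list(group_means = means, p_value = p, counts = counts)
}
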