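#' Run the full synthetic-cohort analysis pipeline
#'
#' Orchestrates the stages end-to-end into a run directory: simulate (or
#' load) a training and a validation cohort with survival outcomes and MSP
#' call matrices, simulate MBD-style count matrices and rank candidate DMRs
#' by pi score with input-background exclusion, train the multimarker
#' signature on the training cohort, apply it frozen to the validation
#' cohort, and write a human-readable report. Every table carries the seed
#' and a config hash in a comment header; a manifest records file checksums.
#' Reruns with the same config and seed are byte-identical.
#'
#' @param outdir run directory (created if absent).
#' @param seed global integer seed; per-stage substreams are derived from
#'   it.
#' @param n_train,n_valid cohort sizes (defaults mirror two MSP cohorts of
#'   148 and 202 patients after ACTB exclusions: 132 and 177).
#' @param sim named list of [sim_config()] overrides applied to both
#'   cohorts.
#' @param framework named list of [meth_signature()] arguments
#'   (e.g. `n_bootstrap`).
#' @param dmr named list of DMR-stage settings: `n_regions`,
#'   `n_per_group`, `effect_log2fc`, `dispersion`, `n_planted`,
#'   `n_background`, `top_k`; set `dmr = NULL` to skip the stage.
#' @param inputs optional named list of TSV paths (`train_calls`,
#'   `train_patients`, `valid_calls`, `valid_patients`) to load instead of
#'   simulating; files must exist.
#' @return invisibly, a list with the fitted signature validation object,
#'   the DMR ranking, and the output paths.
#' @export
run_pipeline <- function(outdir, seed = 1L, n_train = 132L, n_valid = 177L,
                         sim = list(), framework = list(),
                         dmr = list(), inputs = NULL) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  config <- list(seed = seed, n_train = n_train, n_valid = n_valid,
                 sim = sim, framework = framework, dmr = dmr,
                 inputs = inputs)
  config_path <- file.path(outdir, "config.json")
  jsonlite::write_json(config, config_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, null = "null")
  chash <- unname(tools::md5sum(config_path))
  hdr <- list(seed = seed, config = chash)

  load_or_simulate <- function(which, n, sub_seed, panel = NULL) {
    if (!is.null(inputs)) {
      cp <- inputs[[paste0(which, "_calls")]]
      pp <- inputs[[paste0(which, "_patients")]]
      for (p in c(cp, pp)) if (!file.exists(p))
        stop("input file does not exist: ", p)
      patients <- read_tsv(pp)
      raw <- read_tsv(cp, check.names = FALSE)
      calls <- as.matrix(raw[, -1, drop = FALSE])
      rownames(calls) <- raw[[1]]
      storage.mode(calls) <- "integer"
      list(patients = patients, calls = calls, planted = character(0))
    } else {
      cfg <- do.call(sim_config, modifyList(
        list(n_patients = n, seed = sub_seed), sim))
      patients <- simulate_survival(simulate_cohort(cfg), cfg)
      sc <- simulate_calls(patients, cfg, prognostic_assays = panel)
      list(patients = patients, calls = sc$calls,
           planted = sc$prognostic_assays)
    }
  }

  train <- load_or_simulate("train", n_train, seed)
  # the validation cohort is measured with the same assay panel, so the
  # prognostic assays planted in training stay prognostic here
  valid <- load_or_simulate("valid", n_valid, seed + 1L,
                            panel = train$planted)
  write_cohort_tsv(train$patients, file.path(outdir, "patients_train.tsv"),
                   seed)
  write_cohort_tsv(valid$patients,
                   file.path(outdir, "patients_validation.tsv"), seed)
  write_calls_tsv(train$calls, file.path(outdir, "calls_train.tsv"), seed)
  write_calls_tsv(valid$calls, file.path(outdir, "calls_validation.tsv"),
                  seed)

  # DMR discovery stage on simulated MBD-style counts
  dmr_ranking <- NULL
  if (!is.null(dmr)) {
    dcfg <- modifyList(list(n_regions = 1000L, n_per_group = 20L,
                            effect_log2fc = 2, dispersion = 0.1,
                            n_planted = 10L, n_background = 5L,
                            top_k = 20L), dmr)
    groups <- rep(c("A", "B"), each = dcfg$n_per_group)
    cnt <- simulate_counts(dcfg$n_regions, groups,
                           effect_log2fc = dcfg$effect_log2fc,
                           dispersion = dcfg$dispersion,
                           n_planted_dmrs = dcfg$n_planted,
                           n_background_regions = dcfg$n_background,
                           seed = seed)
    enr <- differential_test(cnt$enriched, groups)
    inp <- differential_test(cnt$input, groups)
    dmr_ranking <- rank_dmrs(enr, inp, top_k = dcfg$top_k)
    dmr_ranking$planted <- dmr_ranking$region_id %in% cnt$planted_dmrs
    write_tsv(dmr_ranking, file.path(outdir, "dmr_ranking.tsv"), hdr)
  }

  # signature training on cohort I, frozen validation on cohort II
  fw_args <- c(list(train_calls = train$calls,
                    train_outcome = train$patients$os_event,
                    valid_calls = valid$calls,
                    valid_outcome = valid$patients$os_event,
                    seed = seed), framework)
  tv <- do.call(train_and_validate, fw_args)
  write_tsv(tv$fit$grid, file.path(outdir, "candidate_grid.tsv"), hdr)
  jsonlite::write_json(
    list(assay_set = tv$fit$assay_set, metric = tv$fit$metric,
         assay_cutoff_pct = tv$fit$assay_cutoff_pct,
         score_cutoff_pct = tv$fit$score_cutoff_pct,
         evaluation = tv$fit$evaluation,
         weights = as.list(tv$fit$weights),
         n_bootstrap = tv$fit$n_bootstrap, seed = seed,
         config = chash),
    file.path(outdir, "signature.json"), auto_unbox = TRUE, pretty = TRUE,
    digits = NA)
  write_tsv(tv$predictions$train,
            file.path(outdir, "predictions_train.tsv"), hdr)
  write_tsv(tv$predictions$validation,
            file.path(outdir, "predictions_validation.tsv"), hdr)

  # KM curve tables per cohort and predicted risk group
  for (which in c("train", "validation")) {
    pt <- if (which == "train") train$patients else valid$patients
    pr <- tv$predictions[[which]]
    km_tab <- do.call(rbind, lapply(levels(pr$risk), function(r) {
      idx <- which(pr$risk == r)
      if (length(idx) < 1L) return(NULL)
      km <- km_estimate(pt$os_time_days[idx], pt$os_event[idx])
      if (nrow(km$table) == 0L) return(NULL)
      cbind(risk_group = r, km$table)
    }))
    write_tsv(km_tab, file.path(outdir, sprintf("km_%s.tsv", which)), hdr)
  }

  make_report(outdir)
  files <- sort(list.files(outdir, full.names = TRUE))
  files <- files[!basename(files) %in% "manifest.json"]
  manifest <- list(seed = seed, config = chash,
                   files = lapply(files, function(f)
                     list(name = basename(f),
                          md5 = unname(tools::md5sum(f)))))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(validation = tv, dmr_ranking = dmr_ranking,
                 outdir = outdir))
}

read_calls_tsv <- function(path) {
  raw <- read_tsv(path, check.names = FALSE)
  calls <- as.matrix(raw[, -1, drop = FALSE])
  rownames(calls) <- raw[[1]]
  storage.mode(calls) <- "integer"
  calls
}

per_assay_logrank <- function(calls, patients) {
  vapply(colnames(calls), function(a) {
    cl <- calls[, a]
    ok <- !is.na(cl)
    if (length(unique(cl[ok])) < 2L || sum(patients$os_event[ok]) == 0L)
      return(NA_real_)
    logrank_test(patients$os_time_days[ok], patients$os_event[ok],
                 cl[ok])$p_value
  }, numeric(1))
}

#' Summarise a completed pipeline run
#'
#' Builds a plain-text report from a run directory: individually prognostic
#' assays (log-rank p < 0.05 for overall survival in both cohorts),
#' Fisher-exact associations of those assays and of the signature
#' predictions with the simulated risk factors (MYCN amplification, age at
#' diagnosis, INSS stage 4), five-year survival estimates with confidence
#' intervals per predicted risk group, and the selected signature
#' parameters.
#'
#' @param run_dir directory produced by [run_pipeline()].
#' @return the report lines, invisibly; also written to
#'   `<run_dir>/report.txt`.
#' @export
make_report <- function(run_dir) {
  need <- c("patients_train.tsv", "patients_validation.tsv",
            "calls_train.tsv", "calls_validation.tsv",
            "predictions_train.tsv", "predictions_validation.tsv",
            "signature.json")
  missing <- need[!file.exists(file.path(run_dir, need))]
  if (length(missing))
    stop("incomplete run directory, missing: ",
         paste(missing, collapse = ", "))
  pt <- read_tsv(file.path(run_dir, "patients_train.tsv"))
  pv <- read_tsv(file.path(run_dir, "patients_validation.tsv"))
  ct <- read_calls_tsv(file.path(run_dir, "calls_train.tsv"))
  cv <- read_calls_tsv(file.path(run_dir, "calls_validation.tsv"))
  prt <- read_tsv(file.path(run_dir, "predictions_train.tsv"))
  prv <- read_tsv(file.path(run_dir, "predictions_validation.tsv"))
  sig <- jsonlite::read_json(file.path(run_dir, "signature.json"),
                             simplifyVector = TRUE)

  p_train <- per_assay_logrank(ct, pt)
  p_valid <- per_assay_logrank(cv, pv)
  prognostic <- names(p_train)[!is.na(p_train) & !is.na(p_valid) &
                                 p_train < 0.05 & p_valid < 0.05]

  assoc_row <- function(flag, factor_levels) {
    tab <- table(factor(flag, levels = c(FALSE, TRUE)), factor_levels)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) return(NA_real_)
    fisher_exact(tab)$p_value
  }
  risk_factors <- function(patients) list(
    mycn = patients$mycn_amplified,
    age_gt_12m = patients$age_at_diagnosis_months > 12,
    age_gt_18m = patients$age_at_diagnosis_months > 18,
    stage_4 = patients$inss_stage == 4)

  lines <- c(
    "Synthetic-cohort methylation signature report",
    "=============================================",
    "",
    sprintf("Training cohort: %d patients (%d OS events); validation: %d (%d events)",
            nrow(pt), sum(pt$os_event), nrow(pv), sum(pv$os_event)),
    "",
    sprintf("Individually prognostic assays (OS log-rank p < 0.05 in both cohorts): %d",
            length(prognostic)),
    if (length(prognostic))
      strwrap(paste(prognostic, collapse = ", "), width = 76,
              prefix = "  ") else "  (none)",
    "")

  if (length(prognostic)) {
    rf <- risk_factors(pt)
    lines <- c(lines,
               "Associations of prognostic assays with risk factors (training cohort, Fisher p):")
    for (a in prognostic) {
      ps <- vapply(rf, function(f) {
        ok <- !is.na(ct[, a])
        assoc_row(ct[ok, a] == 1L, f[ok])
      }, numeric(1))
      lines <- c(lines, sprintf("  %s: %s", a,
                                paste(sprintf("%s=%.3g", names(ps), ps),
                                      collapse = " ")))
    }
    lines <- c(lines, "")
  }

  lines <- c(lines,
             "Selected signature:",
             sprintf("  %d assays (%s ranking, %g%% assay cutoff), score cutoff %g%%",
                     length(sig$assay_set), sig$metric,
                     sig$assay_cutoff_pct, sig$score_cutoff_pct),
             sprintf("  training BAC %.4f, event-%% score %.4f, mean Jaccard %.4f, combined %.4f",
                     sig$evaluation$bac, sig$evaluation$event_pct_score,
                     sig$evaluation$mean_jaccard, sig$evaluation$combined),
             "")

  for (which in c("train", "validation")) {
    patients <- if (which == "train") pt else pv
    pred <- if (which == "train") prt else prv
    lines <- c(lines, sprintf("Cohort: %s", which))
    both <- length(unique(pred$risk[!is.na(pred$risk)])) == 2L
    if (both && sum(patients$os_event) > 0) {
      lr <- logrank_test(patients$os_time_days, patients$os_event,
                         pred$risk)
      lines <- c(lines, sprintf("  OS log-rank high vs low risk: chi2 %.3f, p %.3g",
                                lr$chi_square, lr$p_value))
    }
    for (r in c("low", "high")) {
      idx <- which(pred$risk == r)
      if (length(idx) < 2L) next
      km <- km_estimate(patients$os_time_days[idx],
                        patients$os_event[idx])
      s5 <- km_survival_at(km, 5 * 365.25)
      lines <- c(lines, sprintf("  5-year OS, %s-risk group (n=%d): %.2f%% (95%% CI %.2f - %.2f)",
                                r, length(idx), 100 * s5$survival,
                                100 * s5$ci_lower, 100 * s5$ci_upper))
    }
    rf <- risk_factors(patients)
    ps <- vapply(rf, function(f) assoc_row(pred$risk == "high", f),
                 numeric(1))
    lines <- c(lines, sprintf("  signature vs risk factors (Fisher p): %s",
                              paste(sprintf("%s=%.3g", names(ps), ps),
                                    collapse = " ")), "")
  }

  writeLines(lines, file.path(run_dir, "report.txt"))
  invisible(lines)
}
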