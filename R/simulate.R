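#' Configuration for synthetic-cohort simulation
#'
#' Bundles every parameter of the synthetic-cohort generator: cohort
#' composition over the three prognostic groups (low-risk survivors
#' `LR-SURV`, high-risk survivors `HR-SURV`, high-risk deceased `HR-DOD`),
#' the MSP assay panel (how many assays, how many carry true prognostic
#' signal), per-group methylation probabilities, per-call missingness,
#' censoring, and the exponential hazards that drive survival times.
#'
#' Defaults emulate the data structure of a neuroblastoma MSP study: 78
#' assays of which 20 are truly prognostic, methylation probability 0.6 for
#' prognostic assays in deceased patients versus 0.1 otherwise, and hazards
#' chosen so that roughly half of the deceased group's events fall within
#' five years while survivors have a median follow-up of about six years.
#'
#' @param n_patients number of patients to simulate.
#' @param group_proportions probabilities for (LR-SURV, HR-SURV, HR-DOD);
#'   must sum to 1.
#' @param n_assays size of the MSP assay panel.
#' @param n_prognostic_assays number of planted prognostic assays
#'   (`<= n_assays`).
#' @param p_meth_event methylation probability of a prognostic assay in a
#'   patient who dies of disease.
#' @param p_meth_noevent methylation probability of a prognostic assay in a
#'   survivor; must be below `p_meth_event`.
#' @param p_meth_background methylation probability of non-prognostic assays
#'   in all groups.
#' @param missing_rate per-call probability of a missing (unevaluable) call.
#' @param censoring_rate probability that a survivor's follow-up is cut
#'   short by early (uniform) administrative censoring.
#' @param hazard_high exponential death hazard per day for HR-DOD patients.
#' @param hazard_low exponential end-of-follow-up hazard per day for
#'   survivors.
#' @param seed integer seed; all `simulate_*` functions derive deterministic
#'   per-stage substreams from it.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_patients = 132L,
                       group_proportions = c(0.40, 0.30, 0.30),
                       n_assays = 78L,
                       n_prognostic_assays = 20L,
                       p_meth_event = 0.6,
                       p_meth_noevent = 0.1,
                       p_meth_background = 0.1,
                       missing_rate = 0.02,
                       censoring_rate = 0.2,
                       hazard_high = 5e-4,
                       hazard_low = 3e-4,
                       seed = 1L) {
  if (!is.numeric(n_patients) || length(n_patients) != 1L || n_patients < 1)
    stop("n_patients must be a positive integer")
  if (length(group_proportions) != 3L || any(group_proportions < 0) ||
      abs(sum(group_proportions) - 1) > 1e-9)
    stop("group_proportions must be three non-negative values summing to 1")
  if (n_prognostic_assays > n_assays)
    stop("n_prognostic_assays must not exceed n_assays")
  if (p_meth_event <= p_meth_noevent)
    stop("p_meth_event must exceed p_meth_noevent (hypermethylation in poor outcome)")
  for (p in c(p_meth_event, p_meth_noevent, p_meth_background,
              missing_rate, censoring_rate))
    if (!is_prob(p)) stop("probabilities must lie in [0, 1]")
  if (hazard_high <= 0 || hazard_low <= 0) stop("hazards must be positive")
  structure(list(
    n_patients = as.integer(n_patients),
    group_proportions = group_proportions,
    n_assays = as.integer(n_assays),
    n_prognostic_assays = as.integer(n_prognostic_assays),
    p_meth_event = p_meth_event,
    p_meth_noevent = p_meth_noevent,
    p_meth_background = p_meth_background,
    missing_rate = missing_rate,
    censoring_rate = censoring_rate,
    hazard_high = hazard_high,
    hazard_low = hazard_low,
    seed = as.integer(seed)
  ), class = "sim_config")
}

prognostic_groups <- c("LR-SURV", "HR-SURV", "HR-DOD")

#' Simulate a cohort of patients
#'
#' Draws patients into the three prognostic groups by a seeded multinomial
#' draw and assigns risk covariates with group-conditional probabilities, so
#' that the high-risk groups are enriched for INSS stage 4, MYCN
#' amplification and age above 18 months at diagnosis. Overall-survival
#' event indicators follow group membership by construction: only HR-DOD
#' patients die of disease. Survival times are filled in separately by
#' [simulate_survival()].
#'
#' @param config a [sim_config()].
#' @return a data.frame with one row per patient: `patient_id`,
#'   `prognostic_group`, `mycn_amplified`, `inss_stage`,
#'   `age_at_diagnosis_months`, and (initially `NA`) survival columns
#'   `os_time_days`, `os_event`, `efs_time_days`, `efs_event`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_patients
  with_seed(stage_seed(config$seed, "cohort"), {
    grp <- sample(prognostic_groups, n, replace = TRUE,
                  prob = config$group_proportions)
    grp <- factor(grp, levels = prognostic_groups)
    # group-conditional covariates: high-risk groups enriched for stage 4,
    # MYCN amplification and age > 18 months
    p_mycn <- c(`LR-SURV` = 0.02, `HR-SURV` = 0.30, `HR-DOD` = 0.50)[grp]
    mycn <- runif(n) < p_mycn
    stage <- integer(n)
    for (g in prognostic_groups) {
      idx <- which(grp == g)
      probs <- switch(g,
        `LR-SURV` = c(0.50, 0.30, 0.18, 0.02),
        `HR-SURV` = c(0.05, 0.05, 0.20, 0.70),
        `HR-DOD`  = c(0.02, 0.03, 0.10, 0.85))
      if (length(idx)) stage[idx] <- sample(1:4, length(idx), replace = TRUE,
                                            prob = probs)
    }
    age <- ifelse(grp == "LR-SURV",
                  rlnorm(n, meanlog = log(10), sdlog = 0.9),
                  rlnorm(n, meanlog = log(32), sdlog = 0.6))
    data.frame(
      patient_id = sprintf("P%04d", seq_len(n)),
      prognostic_group = grp,
      mycn_amplified = mycn,
      inss_stage = stage,
      age_at_diagnosis_months = age,
      os_time_days = NA_real_,
      os_event = grp == "HR-DOD",
      efs_time_days = NA_real_,
      efs_event = NA,
      stringsAsFactors = FALSE
    )
  })
}

#' Simulate overall and event-free survival times
#'
#' Death times for HR-DOD patients are exponential with rate `hazard_high`;
#' survivor follow-up times are exponential with rate `hazard_low`, with a
#' fraction `censoring_rate` of survivors censored early at a uniform point
#' of their drawn follow-up. Event-free survival is generated as the minimum
#' of a latent relapse time (group-specific relapse hazard, always at least
#' the death hazard for deceased patients) and the overall-survival time, so
#' `efs_time_days <= os_time_days` always holds and every death is also an
#' EFS event.
#'
#' @param patients data.frame from [simulate_cohort()].
#' @param config the same [sim_config()].
#' @return `patients` with `os_time_days`, `os_event`, `efs_time_days`,
#'   `efs_event` filled in.
#' @export
simulate_survival <- function(patients, config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$hazard_high <= 0 || config$hazard_low <= 0)
    stop("hazards must be positive")
  n <- nrow(patients)
  with_seed(stage_seed(config$seed, "survival"), {
    grp <- as.character(patients$prognostic_group)
    dod <- grp == "HR-DOD"
    t <- numeric(n)
    t[dod] <- rexp(sum(dod), rate = config$hazard_high)
    t[!dod] <- rexp(sum(!dod), rate = config$hazard_low)
    cens <- !dod & runif(n) < config$censoring_rate
    t[cens] <- t[cens] * runif(sum(cens))
    patients$os_time_days <- t
    patients$os_event <- dod
    # latent relapse: deceased relapse at >= their death hazard; survivors may
    # have had a relapse event before last follow-up (HR-SURV more than LR)
    relapse_rate <- ifelse(dod, 1.5 * config$hazard_high,
                           ifelse(grp == "HR-SURV", 0.3 * config$hazard_low,
                                  0.05 * config$hazard_low))
    r <- rexp(n, rate = relapse_rate)
    patients$efs_time_days <- pmin(r, t)
    patients$efs_event <- dod | (r < t)
    patients
  })
}

#' Simulate an MSP call matrix with planted prognostic assays
#'
#' Produces a ternary (methylated = 1, unmethylated = 0, missing = `NA`)
#' samples-by-assays matrix. The first `n_prognostic_assays` assays (chosen
#' by seeded draw) are methylated with probability `p_meth_event` in HR-DOD
#' patients and `p_meth_noevent` in survivors; all other assays use
#' `p_meth_background` in every group. Calls are independently set to
#' missing with probability `missing_rate`. The identities of the planted
#' assays are returned for recovery testing.
#'
#' @param patients data.frame from [simulate_cohort()].
#' @param config a [sim_config()].
#' @param prognostic_assays optional character vector fixing which assays
#'   carry the prognostic signal. The prognostic markers are a property of
#'   the assay panel, not of a cohort: when simulating several cohorts
#'   measured with one panel (e.g. training and validation), pass the
#'   panel returned by the first call so the same assays are prognostic in
#'   every cohort. `NULL` draws a fresh seeded subset.
#' @return list with `calls` (integer matrix, rownames = patient ids,
#'   colnames = assay ids) and `prognostic_assays` (character vector).
#' @export
simulate_calls <- function(patients, config, prognostic_assays = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (nrow(patients) == 0L) stop("empty patient list")
  n <- nrow(patients)
  m <- config$n_assays
  with_seed(stage_seed(config$seed, "calls"), {
    assay_ids <- sprintf("assay%03d", seq_len(m))
    planted <- if (is.null(prognostic_assays))
      sort(sample(assay_ids, config$n_prognostic_assays))
    else sort(as.character(prognostic_assays))
    if (!all(planted %in% assay_ids))
      stop("prognostic_assays must be drawn from the assay panel")
    event <- patients$prognostic_group == "HR-DOD"
    p <- matrix(config$p_meth_background, nrow = n, ncol = m,
                dimnames = list(patients$patient_id, assay_ids))
    p[, planted] <- ifelse(event, config$p_meth_event, config$p_meth_noevent)
    calls <- matrix(as.integer(runif(n * m) < p), nrow = n,
                    dimnames = dimnames(p))
    calls[runif(n * m) < config$missing_rate] <- NA_integer_
    list(calls = calls, prognostic_assays = planted)
  })
}

#' Simulate MBD-seq style region count matrices
#'
#' Draws negative-binomial counts over a region set for two sample groups,
#' with region-specific log-normal base means, per-sample depth multipliers
#' and a `2^effect_log2fc` mean shift in group B for the planted
#' differentially methylated regions. A matched "input" (non-enriched)
#' matrix is generated with no group effect, except in
#' `n_background_regions` background-artifact regions, which shift in both
#' the enriched and input matrices (copy-number-like artifacts that the
#' input-background exclusion should catch).
#'
#' @param regions a region set data.frame (see [make_windows()]), or an
#'   integer number of anonymous regions.
#' @param group_assignment vector of "A"/"B" per sample.
#' @param effect_log2fc log2 fold change planted in group B.
#' @param dispersion negative-binomial dispersion (variance =
#'   `mu + dispersion * mu^2`); must be positive.
#' @param depth_factors positive per-sample depth multipliers (recycled to
#'   the number of samples).
#' @param n_planted_dmrs number of regions carrying the true group effect.
#' @param n_background_regions number of artifact regions shifting in both
#'   matrices.
#' @param seed integer seed.
#' @return list with `enriched` and `input` count matrices (regions x
#'   samples), `planted_dmrs` and `background_regions` (region ids), and
#'   `group_assignment`.
#' @export
simulate_counts <- function(regions, group_assignment,
                            effect_log2fc = 2, dispersion = 0.1,
                            depth_factors = 1,
                            n_planted_dmrs = 10L,
                            n_background_regions = 5L,
                            seed = 1L) {
  if (dispersion <= 0) stop("dispersion must be positive")
  if (any(depth_factors <= 0)) stop("depth factors must be positive")
  region_ids <- if (is.data.frame(regions)) regions$region_id
                else sprintf("region%04d", seq_len(regions))
  nr <- length(region_ids)
  ns <- length(group_assignment)
  if (!all(group_assignment %in% c("A", "B")))
    stop("group_assignment must be 'A'/'B'")
  depth <- rep_len(depth_factors, ns)
  with_seed(stage_seed(seed, "counts"), {
    planted <- sort(sample(region_ids, n_planted_dmrs))
    background <- sort(sample(setdiff(region_ids, planted),
                              n_background_regions))
    base_mu <- rlnorm(nr, meanlog = log(50), sdlog = 1)
    names(base_mu) <- region_ids
    g_b <- group_assignment == "B"
    draw <- function(mu_mat) {
      size <- 1 / dispersion
      matrix(rnbinom(nr * ns, size = size, mu = as.vector(mu_mat)),
             nrow = nr, dimnames = list(region_ids,
                                        sprintf("S%03d", seq_len(ns))))
    }
    mu_enr <- outer(base_mu, depth)
    mu_enr[planted, g_b] <- mu_enr[planted, g_b] * 2^effect_log2fc
    mu_enr[background, g_b] <- mu_enr[background, g_b] * 2^effect_log2fc
    mu_inp <- outer(base_mu, depth)
    mu_inp[background, g_b] <- mu_inp[background, g_b] * 2^effect_log2fc
    list(enriched = draw(mu_enr), input = draw(mu_inp),
         planted_dmrs = planted, background_regions = background,
         group_assignment = group_assignment)
  })
}

#' Write a simulated cohort to TSV
#'
#' One row per patient; ISO-style column names; `NA` for missing values.
#'
#' @param patients cohort data.frame.
#' @param path output file.
#' @param seed seed recorded in the file header.
#' @export
write_cohort_tsv <- function(patients, path, seed = NA) {
  write_tsv(patients, path, header_fields = list(seed = seed))
}

#' Write a call matrix to TSV (samples as rows, assays as columns)
#' @param calls integer matrix in \{1, 0, NA\}.
#' @param path output file.
#' @param seed seed recorded in the file header.
#' @export
write_calls_tsv <- function(calls, path, seed = NA) {
  df <- data.frame(sample_id = rownames(calls), calls, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv(df, path, header_fields = list(seed = seed))
}
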