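test_that("per-assay metrics match the confusion-table definitions", {
  # one assay: TP=3, FN=1 among events; TN=4, FP=2 among survivors
  calls <- make_calls(c(1L, 1L, 1L, 0L, 1L, 1L, 0L, 0L, 0L, 0L), 10,
                      "assayA")
  outcome <- c(rep(TRUE, 4), rep(FALSE, 6))
  m <- assay_metrics(calls, outcome)
  expect_equal(m$tpr, 0.75)
  expect_equal(m$tnr, 2 / 3, tolerance = 1e-9)
  expect_equal(m$bac, (0.75 + 2 / 3) / 2, tolerance = 1e-9)

  perfect <- make_calls(as.integer(outcome), 10, "assayB")
  expect_equal(unlist(assay_metrics(perfect, outcome)[, 2:4]),
               c(tpr = 1, tnr = 1, bac = 1))
  never <- make_calls(rep(0L, 10), 10, "assayC")
  expect_equal(unlist(assay_metrics(never, outcome)[, 2:4]),
               c(tpr = 0, tnr = 1, bac = 0.5))
  expect_error(assay_metrics(calls, rep(TRUE, 10)), "both classes")

  # BAC depends only on the confusion table: swapping sample identities
  # within classes changes nothing
  perm <- c(sample(1:4), sample(5:10))
  expect_equal(assay_metrics(calls[perm, , drop = FALSE], outcome[perm]),
               m)
})

test_that("assay selection applies the ceiling percentile rule", {
  metrics <- data.frame(assay_id = sprintf("a%02d", 1:78),
                        tpr = seq(1, 0, length.out = 78),
                        tnr = 0.5, bac = seq(0.5, 1, length.out = 78))
  expect_length(select_assays(metrics, "TPR", 100), 78)
  expect_length(select_assays(metrics, "TPR", 50), 39)
  expect_equal(select_assays(metrics, "TPR", 0), "a01")
  expect_equal(select_assays(metrics, "BAC", 0), "a78")
  # ties broken by assay id ascending
  tied <- data.frame(assay_id = c("z", "a", "m"), tpr = 0.5, tnr = 0.5,
                     bac = 0.5)
  expect_equal(select_assays(tied, "BAC", 20), "a")
  expect_equal(select_assays(tied, "BAC", 34), c("a", "m"))
  expect_error(select_assays(metrics[0, ], "BAC", 50), "empty")
})

test_that("risk prediction uses a strict score cutoff", {
  expect_equal(as.character(predict_risk(30, 25)), "high")
  expect_equal(as.character(predict_risk(25, 25)), "low")
  expect_equal(as.character(predict_risk(0, 0)), "low")
  expect_true(is.na(predict_risk(NA, 25)))
})

test_that("the candidate grid enumerates the full Cartesian product", {
  grid <- enumerate_candidates()
  expect_equal(nrow(grid), 1323)
  expect_length(unique(grid$assay_cutoff_pct), 21)
  expect_length(unique(grid$score_cutoff_pct), 21)
  expect_equal(nrow(enumerate_candidates(metrics = "BAC")), 441)
  expect_equal(nrow(enumerate_candidates(assay_cutoffs = c(0, 50, 100),
                                         score_cutoffs = c(0, 50, 100))),
               27)
  # deterministic order: metric slowest, then assay cutoff, then score
  expect_equal(grid$metric[1:441], rep("TPR", 441))
  expect_equal(grid$assay_cutoff_pct[1:42], rep(c(0, 5), each = 21))
  expect_equal(grid$score_cutoff_pct[1:21], seq(0, 100, 5))
  expect_error(enumerate_candidates(metrics = character(0)), "empty")
})

test_that("signature evaluation scores predictions against outcome", {
  outcome <- c(rep(TRUE, 3), rep(FALSE, 7))
  perfect <- methsig:::evaluate_predictions(outcome, outcome)
  expect_equal(perfect$bac, 1)
  expect_equal(perfect$event_pct_score, 1)

  ev <- methsig:::evaluate_predictions(c(rep(TRUE, 4), rep(FALSE, 6)),
                                       c(rep(TRUE, 3), rep(FALSE, 7)))
  expect_equal(ev$event_pct_score, 0.9)

  half <- methsig:::evaluate_predictions(rep(FALSE, 10),
                                         rep(c(TRUE, FALSE), 5))
  expect_equal(half$bac, 0.5)
  expect_equal(half$event_pct_score, 0.5)
})

test_that("Jaccard similarity follows the set definition", {
  expect_equal(jaccard_index(c("a", "b"), c("a", "b")), 1)
  expect_equal(jaccard_index("a", "b"), 0)
  expect_equal(jaccard_index(c("a", "b", "c"), c("b", "c", "d")), 0.5)
  expect_equal(jaccard_index(character(0), character(0)), 1)
})

test_that("the weighted harmonic mean combines and zeroes correctly", {
  w <- c(1, 1, 1)
  expect_equal(methsig:::combine_harmonic(c(1, 1, 1), w), 1)
  expect_equal(methsig:::combine_harmonic(c(0.5, 1, 1), w), 0.75)
  expect_equal(methsig:::combine_harmonic(c(0.9, 0, 1), w), 0)
  # harmonic-mean bounds: between the min component and the arithmetic mean
  set.seed(5)
  for (i in 1:50) {
    x <- runif(3, 0.05, 1)
    h <- methsig:::combine_harmonic(x, w)
    expect_gte(h, min(x) - 1e-12)
    expect_lte(h, mean(x) + 1e-12)
  }
  # weights tilt the mean toward the heavily weighted component
  expect_gt(methsig:::combine_harmonic(c(0.5, 1, 1), c(1, 5, 5)),
            methsig:::combine_harmonic(c(0.5, 1, 1), w))
})

test_that("bootstrap robustness is 1 for forced or degenerate selections", {
  cfg <- sim_config(n_patients = 40, seed = 23)
  co <- simulate_cohort(cfg)
  sc <- simulate_calls(co, cfg)
  # cutoff 100%: every subcohort selects all assays
  expect_equal(bootstrap_robustness(sc$calls, co$os_event, "BAC", 100,
                                    n_bootstrap = 20, seed = 1), 1)
  # identical metric values everywhere: deterministic tie-break by id
  flat <- make_calls(rep(c(1L, 0L), each = 60), 4,
                     sprintf("f%02d", 1:30))
  expect_equal(bootstrap_robustness(flat, c(TRUE, TRUE, FALSE, FALSE),
                                    "BAC", 50, n_bootstrap = 20,
                                    seed = 2), 1)
})

test_that("planted structure yields higher bootstrap stability than noise", {
  wins <- vapply(1:10, function(s) {
    cfg <- sim_config(n_patients = 80, seed = 400 + s)
    co <- simulate_cohort(cfg)
    sc <- simulate_calls(co, cfg)
    jac_true <- bootstrap_robustness(sc$calls, co$os_event, "BAC", 25,
                                     n_bootstrap = 30, seed = s)
    set.seed(9000 + s)
    perm <- sample(co$os_event)   # permuted labels
    jac_perm <- bootstrap_robustness(sc$calls, perm, "BAC", 25,
                                     n_bootstrap = 30, seed = s)
    jac_true > jac_perm
  }, logical(1))
  expect_gte(mean(wins), 0.9)
})

test_that("meth_signature fits, recovers planted assays and is deterministic", {
  cfg <- sim_config(n_patients = 100, seed = 55)
  co <- simulate_cohort(cfg)
  sc <- simulate_calls(co, cfg)
  fit <- meth_signature(sc$calls, co$os_event, n_bootstrap = 30, seed = 55)
  expect_s3_class(fit, "meth_signature")
  expect_equal(nrow(fit$grid), 1323)
  # recovered assay set is dominated by planted assays
  expect_gt(length(intersect(fit$assay_set, sc$prognostic_assays)) /
              length(fit$assay_set), 0.5)
  expect_gt(fit$evaluation$bac, 0.8)
  # pure function of (data, config, seed)
  fit2 <- meth_signature(sc$calls, co$os_event, n_bootstrap = 30,
                         seed = 55)
  expect_equal(fit$grid, fit2$grid)
  expect_identical(fit$assay_set, fit2$assay_set)
  # harmonic-mean bounds hold across the whole grid
  pos <- fit$grid$combined > 0
  comp <- fit$grid[pos, c("bac", "event_pct_score", "mean_jaccard")]
  expect_true(all(fit$grid$combined[pos] >= do.call(pmin, comp) - 1e-12))
  expect_true(all(fit$grid$combined[pos] <= rowMeans(comp) + 1e-12))
  # S3 surface
  expect_output(print(fit), "Multimarker")
  expect_output(print(summary(fit)), "Top candidates")
  expect_equal(names(coef(fit)), fit$assay_set)
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
})

test_that("train/validate freezes the signature and matches on identity", {
  cfg <- sim_config(n_patients = 80, seed = 66)
  co <- simulate_cohort(cfg)
  sc <- simulate_calls(co, cfg)
  tv <- train_and_validate(sc$calls, co$os_event, sc$calls, co$os_event,
                           n_bootstrap = 20, seed = 66)
  expect_identical(tv$predictions$train, tv$predictions$validation)
  expect_equal(tv$evaluation$train$bac, tv$evaluation$validation$bac)
  expect_error(train_and_validate(sc$calls, co$os_event,
                                  sc$calls[, 1:10], co$os_event,
                                  n_bootstrap = 5, seed = 1),
               "universe")
})
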