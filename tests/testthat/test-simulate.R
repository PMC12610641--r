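test_that("the generator is deterministic given a seed", {
  s1 <- simulate_dataset(sim_config(seed = 17))
  s2 <- simulate_dataset(sim_config(seed = 17))
  expect_identical(s1$voc, s2$voc)
  expect_identical(s1$thresholds, s2$thresholds)
  expect_identical(s1$panel, s2$panel)
  expect_identical(s1$truth$mu, s2$truth$mu)
  s3 <- simulate_dataset(sim_config(seed = 18))
  expect_false(identical(s1$voc$mean, s3$voc$mean))
})

test_that("generated tables satisfy the container invariants", {
  sim <- simulate_dataset(sim_config(seed = 23))
  expect_s3_class(sim$voc, "voc_table")
  expect_true(all(sim$voc$mean >= 0))
  expect_identical(sim$voc$detected, sim$voc$mean > 0)
  # percent sums are exactly 100 for every cultivar
  expect_equal(unname(colSums(sim$voc$mean)), rep(100, 3),
               tolerance = 1e-9)
  expect_s3_class(sim$thresholds, "threshold_db")
  expect_true(all(sim$thresholds$value > 0))
  expect_s3_class(sim$panel, "sensory_panel")
  expect_true(all(sim$panel$score >= 0 & sim$panel$score <= 10))
  expect_identical(nrow(sim$panel), 756L)
})

test_that("the detection design is recovered exactly from the output table", {
  cfg <- sim_config(seed = 5)
  sim <- simulate_dataset(cfg)
  det <- detection_sets(sim$voc)
  expect_identical(length(det$shared_all), 19L)
  expect_identical(unname(vapply(det$unique_per_sample, length, 1L)),
                   c(1L, 7L, 4L))
})

test_that("planted markers land in their target tier with margin", {
  cfg <- sim_config(seed = 29, planted_markers = data.frame(
    cultivar = c("B", "C"), compound = NA_character_,
    tier = c("key", "modifier"), stringsAsFactors = FALSE))
  sim <- simulate_dataset(cfg)
  mk <- sim$truth$markers
  # analytic ROAV from the generating parameters, before noise
  res <- resolve_thresholds(sim$thresholds)
  tv <- setNames(res$value, res$compound)
  for (i in seq_len(nrow(mk))) {
    p <- compute_roav_profile(sim$truth$mu[, mk$cultivar[i]], tv)
    val <- p$roav[mk$compound[i]]
    if (mk$tier[i] == "key") expect_gte(val, 2)
    if (mk$tier[i] == "modifier") {
      expect_gte(val, 0.2); expect_lte(val, 0.5)
    }
    # marker compounds are unique to their cultivar
    expect_true(mk$compound[i] %in%
                  sim$truth$unique_ids[[mk$cultivar[i]]])
  }
})

test_that("noise-free simulation is recovered perfectly by the pipeline", {
  # with (nearly) no noise the expected letter pattern is the one that
  # separates every pair of unequal planted means, so the equivalence
  # band collapses to zero
  cfg <- sim_config(seed = 41, replicate_cv = 0, assessor_sd = 0,
                    residual_sd = 0.05, letter_equiv_tol = 0)
  sim <- simulate_dataset(cfg)
  rt <- roav_table(sim$voc, sim$thresholds)
  lt <- lapply(cfg$attributes, function(a) posthoc_letters(sim$panel, a))
  names(lt) <- cfg$attributes
  agg <- aggregate_scores(sim$panel)
  sm <- with(agg, tapply(mean, list(sample, attribute),
                         identity))[cfg$cultivars, cfg$attributes]
  cm <- t(sim$voc$mean[unique(sim$truth$linked_pairs$compound),
                       cfg$cultivars, drop = FALSE])
  cl <- colocalize(joint_pca(sm, cm), pairs = data.frame(
    compound = sim$truth$coloc$compound,
    attribute = sim$truth$coloc$attribute))
  rep <- recovery_report(sim$truth, roav = rt, letters = lt, coloc = cl)
  expect_equal(rep$tier_accuracy, 1)
  expect_equal(rep$reference_match, 1)
  expect_equal(rep$letter_match, 1)
  expect_equal(rep$coloc_precision, 1)
  expect_equal(rep$coloc_recall, 1)
})

test_that("key-tier recovery stays high under realistic replicate noise", {
  set.seed(1000)
  hits <- total <- 0
  for (seed in 1:100) {
    sim <- simulate_dataset(sim_config(seed = seed))
    rt <- roav_table(sim$voc, sim$thresholds)
    common <- intersect(rownames(rt$tier), rownames(sim$truth$tier))
    truly_key <- sim$truth$tier[common, ] == "key"
    est_key <- rt$tier[common, colnames(sim$truth$tier)] == "key"
    hits <- hits + sum(est_key & truly_key)
    total <- total + sum(truly_key)
  }
  expect_gte(hits / total, 0.95)
})

test_that("shuffled truth labels reduce recovery to chance levels", {
  sim <- simulate_dataset(sim_config(seed = 61))
  rt <- roav_table(sim$voc, sim$thresholds)
  truth_shuffled <- sim$truth
  set.seed(99)
  perm <- sample(nrow(truth_shuffled$tier))
  rownames(truth_shuffled$tier) <-
    rownames(truth_shuffled$tier)[perm]
  rep_true <- recovery_report(sim$truth, roav = rt)
  rep_shuf <- recovery_report(truth_shuffled, roav = rt)
  expect_gt(rep_true$tier_accuracy, 0.9)
  expect_lt(rep_shuf$tier_accuracy, rep_true$tier_accuracy - 0.2)
})

test_that("infeasible marker requests fail before sampling", {
  expect_error(sim_config(planted_markers = data.frame(
    cultivar = "Z", compound = NA_character_, tier = "key")),
    "not among cultivars")
  expect_error(sim_config(planted_markers = data.frame(
    cultivar = "B", compound = NA_character_, tier = "dominant")),
    "tier must be")
  # a marker naming a compound outside its cultivar's unique set
  expect_error(simulate_dataset(sim_config(planted_markers = data.frame(
    cultivar = "A", compound = "cmp01", tier = "key"))),
    "unique to its cultivar")
})
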