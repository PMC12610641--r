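test_that("score aggregation pools sessions with n-1 standard deviations", {
  means <- c(A = 5, B = 5, C = 5)
  panel <- make_panel(means, sd = 0)
  agg <- aggregate_scores(panel)
  expect_equal(agg$mean, rep(5, 3))
  expect_equal(agg$sd, rep(0, 3))
  expect_identical(agg$n, rep(36L, 3))

  # two observations: hand arithmetic
  recs <- data.frame(assessor = c("a1", "a2"), session = 1,
                     sample = "A", attribute = "x", score = c(4, 6))
  agg2 <- aggregate_scores(sensory_panel(recs))
  expect_equal(agg2$mean, 5)
  expect_equal(agg2$sd, sqrt(2))

  # seeded simulation recovery of a planted mean
  set.seed(77)
  p <- make_panel(c(A = 8.2, B = 3, C = 3), sd = 0.7)
  a <- aggregate_scores(p)
  est <- a$mean[a$sample == "A"]
  expect_lt(abs(est - 8.2), 3 * 0.7 / sqrt(36))
})

test_that("one-way ANOVA matches the sums-of-squares formula and null case", {
  # identical groups: F = 0, p = 1
  recs <- expand.grid(assessor = paste0("a", 1:3), session = 1:2,
                      sample = c("A", "B"), attribute = "x",
                      stringsAsFactors = FALSE)
  recs$score <- rep(c(1, 2, 3, 4, 5, 6), 2)
  an <- anova_attribute(sensory_panel(recs), "x")
  expect_equal(an$F, 0, tolerance = 1e-12)
  expect_equal(an$p, 1, tolerance = 1e-12)

  # hand-computed F for {1,2,3} vs {4,5,6}
  recs2 <- data.frame(assessor = rep(paste0("a", 1:3), 2),
                      session = 1,
                      sample = rep(c("A", "B"), each = 3),
                      attribute = "x", score = c(1, 2, 3, 4, 5, 6))
  an2 <- anova_attribute(sensory_panel(recs2), "x")
  expect_equal(an2$F, 13.5, tolerance = 1e-12)
  expect_identical(c(an2$df_between, an2$df_within), c(1, 4))

  # random data vs the textbook formula
  set.seed(12)
  for (i in 1:20) {
    p <- make_panel(c(A = runif(1, 2, 8), B = runif(1, 2, 8),
                      C = runif(1, 2, 8)), sd = runif(1, 0.3, 1.5))
    an3 <- anova_attribute(p, "attr1")
    groups <- split(p$score, p$sample)
    expect_equal(an3$F, oracle_anova_F(groups), tolerance = 1e-9)
  }

  # zero within-group variance with unequal means: flagged 0-limit
  recs3 <- recs2; recs3$score <- rep(c(1, 5), each = 3)
  an4 <- anova_attribute(sensory_panel(recs3), "x")
  expect_true(an4$degenerate)
  expect_identical(an4$p, 0)
})

test_that("planted mean gaps are detected with p < 0.001 in most runs", {
  set.seed(31)
  hits <- 0
  for (i in 1:200) {
    p <- make_panel(c(A = 5.0, B = 6.5, C = 8.0), sd = 0.8)
    if (anova_attribute(p, "attr1")$p < 0.001) hits <- hits + 1
  }
  expect_gte(hits / 200, 0.95)
})

test_that("letter displays encode the significance graph exactly (brute force)", {
  set.seed(88)
  for (i in 1:200) {
    k <- sample(2:5, 1)
    g <- paste0("g", seq_len(k))
    means <- setNames(sort(runif(k, 0, 10), decreasing = TRUE), g)
    sig <- matrix(FALSE, k, k, dimnames = list(g, g))
    for (a in seq_len(k - 1)) for (b in (a + 1):k) {
      sig[a, b] <- sig[b, a] <- runif(1) < 0.5
    }
    lt <- cld_letters(sig, means)
    expect_true(cld_encodes_graph(lt, sig))
    # the highest mean always carries "a"
    expect_true(grepl("a", lt[[names(means)[1]]]))
  }
})

test_that("permuting group labels permutes letters consistently", {
  set.seed(5)
  p <- make_panel(c(A = 3, B = 8, C = 5.5), sd = 0.6)
  lt <- posthoc_letters(p, "attr1")
  relab <- c(A = "C", B = "A", C = "B")
  p2 <- p
  p2$sample <- relab[p2$sample]
  p2 <- sensory_panel(as.data.frame(p2))
  lt2 <- posthoc_letters(p2, "attr1")
  expect_identical(unname(lt2[relab]), unname(lt[names(relab)]))
})

test_that("Tukey letters separate three well-spaced groups as a/b/c", {
  set.seed(19)
  p <- make_panel(c(F023 = 8.5, F055 = 5.5, F054 = 2.9), sd = 0.9)
  lt <- posthoc_letters(p, "attr1", method = "tukey")
  expect_identical(unname(lt[c("F023", "F055", "F054")]),
                   c("a", "b", "c"))
  # homogeneous case: everyone shares "a"
  p0 <- make_panel(c(A = 5, B = 5, C = 5), sd = 0)
  expect_identical(unique(unname(posthoc_letters(p0, "attr1"))), "a")
})

test_that("Duncan's multiple range test agrees with Tukey on clear structure", {
  set.seed(23)
  p <- make_panel(c(A = 8.2, B = 3.0, C = 2.9), sd = 0.7)
  ld <- posthoc_letters(p, "attr1", method = "duncan")
  lt <- posthoc_letters(p, "attr1", method = "tukey")
  expect_identical(ld, lt)
  expect_identical(unname(ld[c("A", "B", "C")]), c("a", "b", "b"))
  expect_error(posthoc_pairs(p, "attr1", method = "scheffe"))
})

test_that("sensory summary assembles means, F, p, and letters per attribute", {
  sim <- simulate_dataset(sim_config(seed = 11))
  s <- sensory_summary(sim$panel)
  expect_identical(nrow(s), 21L)
  expect_true(all(s$mean >= 0 & s$mean <= 10))
  expect_true(all(s$letters != ""))
  woody <- s[s$attribute == "woody", ]
  expect_identical(woody$letters[which.max(woody$mean)], "a")
})
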