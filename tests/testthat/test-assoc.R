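# Trait association: two-group tests, Tukey HSD letters, report assembly.

test_that("identical degenerate groups give p = 1 with a flag", {
  v <- rep(5, 12)
  g <- rep(c("a", "b"), each = 6)
  out <- pairwiseTests(v, g)
  expect_equal(out$p_value, rep(1, 3))
  expect_equal(unique(out$flag), "degenerate")
})

test_that("test p-values match the reference implementations", {
  x <- c(12.1, 14.3, 11.8, 15.2, 13.7, 12.9)
  y <- c(16.4, 17.1, 15.8, 18.2, 16.9, 17.7, 15.5)
  v <- c(x, y); g <- rep(c("a", "b"), c(6, 7))
  out <- pairwiseTests(v, g)
  expect_equal(out$p_value[out$test == "wilcoxon"],
               wilcox.test(x, y, exact = TRUE)$p.value, tolerance = 1e-9)
  expect_equal(out$p_value[out$test == "student_t"],
               t.test(x, y, var.equal = TRUE)$p.value, tolerance = 1e-9)
  expect_equal(out$p_value[out$test == "welch_t"],
               t.test(x, y)$p.value, tolerance = 1e-9)
  expect_match(out$direction[1], "<")
})

test_that("a planted 0.8-SD deficit in a small group is detected with power > 0.8", {
  hits <- 0L
  set.seed(81)
  for (r in 1:500) {
    x <- rnorm(150, 0, 1)
    y <- rnorm(15, -0.8, 1)
    p <- suppressWarnings(wilcox.test(x, y)$p.value)
    if (p <= 0.05) hits <- hits + 1L
  }
  expect_gt(hits / 500, 0.8)
})

test_that("Tukey HSD letters separate distant groups and unite null groups", {
  set.seed(83)
  v <- c(rnorm(12, 0), rnorm(12, 10), rnorm(12, 0.1))
  g <- rep(c("g1", "g2", "g3"), each = 12)
  th <- tukeyHsd(v, g)
  expect_false(grepl(th$letters[["g2"]], th$letters[["g1"]], fixed = TRUE) ||
                 grepl(th$letters[["g1"]], th$letters[["g2"]], fixed = TRUE))
  expect_true(any(strsplit(th$letters[["g1"]], "")[[1]] %in%
                    strsplit(th$letters[["g3"]], "")[[1]]))
  # letters are consistent with the pairwise significance at alpha
  for (i in seq_len(nrow(th$pairs))) {
    pr <- strsplit(th$pairs$comparison[i], "-", fixed = TRUE)[[1]]
    shared <- any(strsplit(th$letters[[pr[1]]], "")[[1]] %in%
                    strsplit(th$letters[[pr[2]]], "")[[1]])
    expect_equal(shared, !th$pairs$significant[i])
  }
  # null case: all groups share a letter nearly always
  share <- 0L
  for (r in 1:60) {
    v0 <- rnorm(36)
    th0 <- tukeyHsd(v0, g)
    if (length(unique(th0$letters)) == 1) share <- share + 1L
  }
  expect_gte(share / 60, 0.9)
})

test_that("the association report covers every trait and flags edge cases", {
  eff <- matrix(0, 1, 20, dimnames = list("SV", defaultPhenoModel()@traits))
  eff["SV", "grain_yield"] <- -9.5
  ph <- simulatePhenotypes(c("intact", "SV"), defaultPhenoModel(eff),
                           nPerGroup = 25, seed = 6)
  rep <- associationReport(ph, "group")
  expect_equal(nrow(rep), 20L)
  expect_true(rep$significant[rep$trait == "grain_yield"])
  expect_false(any(is.na(rep$p_wilcoxon)))
  # only the planted trait should dominate the significant set
  expect_lte(sum(rep$significant), 4L)
  # single-group input: empty result with a warning
  ph1 <- ph[ph$group == "SV", ]
  expect_warning(rep1 <- associationReport(ph1, "group"), "fewer than two")
  expect_equal(nrow(rep1), 0L)
  # multi-group route uses Tukey letters
  ph3 <- simulatePhenotypes(c("g1", "g2", "g3"), defaultPhenoModel(),
                            nPerGroup = 10, seed = 7)
  rep3 <- associationReport(ph3, "group", traits = "grain_yield")
  expect_equal(rep3$test, "tukey_hsd")
  expect_match(rep3$letters, "g1")
})
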