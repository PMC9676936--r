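# SV calling: support threshold, clustering, duplication classification and
# cross-sample merging.

mkSv <- function(ref_id, position, type, length, support = 20L,
                 sample_id = "s1", alt = "") {
  data.frame(ref_id = ref_id, position = as.integer(position), type = type,
             length = as.integer(length), support = as.integer(support),
             sample_id = sample_id, alt = alt, stringsAsFactors = FALSE)
}

test_that("planted SVs are called with exact lengths from error-free reads", {
  sv <- knownSvEdits()
  run <- fxSvRun("b1a", "B", sv[["Vrn-B1a"]])
  calls <- callSVs(run$aln, sample_id = "x")
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$type, "DEL")
  expect_equal(calls$length, 6851L)
  expect_lte(abs(calls$position - 1760L), 10L)
  expect_equal(calls$support, 50L)

  run2 <- fxSvRun("a1a", "A", sv[["Vrn-A1a"]])
  calls2 <- callSVs(run2$aln, sample_id = "x")
  expect_equal(calls2$type, "INS")
  expect_equal(calls2$length, 231L)
})

test_that("calls below the support threshold are suppressed", {
  sv <- knownSvEdits()
  run <- fxSvRun("b1b_9", "B", sv[["Vrn-B1b"]], nReads = 9)
  expect_equal(nrow(callSVs(run$aln, sample_id = "x")), 0L)
  run2 <- fxSvRun("b1b", "B", sv[["Vrn-B1b"]], nReads = 50)
  calls <- callSVs(run2$aln, sample_id = "x")
  expect_equal(calls$length, 37L)
})

test_that("error-free reads without planted SVs give an empty call set", {
  run <- fxSvRun("plainA", "A", alleleEdit())
  expect_equal(nrow(callSVs(run$aln, sample_id = "x")), 0L)
})

test_that("tandem duplications are reclassified from insertions", {
  refs <- fxRefs()
  run <- fxSvRun("b1f", "B", knownSvEdits()[["Vrn-B1f"]])
  calls <- classifyInsertion(callSVs(run$aln, sample_id = "x"), refs$B)
  expect_equal(calls$type, "DUP")
  expect_equal(calls$length, 838L)
  expect_gte(calls$dup_identity, 0.99)
  # random-sequence insertion stays INS
  run2 <- fxSvRun("d1x", "D", knownSvEdits()[["Vrn-D1x"]])
  calls2 <- classifyInsertion(callSVs(run2$aln, sample_id = "x"), refs$D)
  expect_equal(calls2$type, "INS")
  expect_equal(calls2$length, 163L)
  # synthetic: inserted sequence equal to the preceding window
  s <- refSeq(refs$A)
  syn <- mkSv("A", 5000L, "INS", 100L, alt = substr(s, 4901, 5000))
  expect_equal(classifyInsertion(syn, refs$A)$type, "DUP")
  expect_equal(classifyInsertion(syn, refs$A)$dup_identity, 1.0)
  # missing sequence: left INS, flagged
  noseq <- mkSv("A", 5000L, "INS", 100L, alt = "")
  expect_equal(classifyInsertion(noseq, refs$A)$type, "INS")
  expect_equal(classifyInsertion(noseq, refs$A)$flag, "no_sequence")
})

test_that("merging collapses same-type calls within the window only", {
  a <- mkSv("B", 2000L, "DEL", 6851L, sample_id = "s1")
  b <- mkSv("B", 2004L, "DEL", 6851L, sample_id = "s2")
  c3 <- mkSv("B", 1998L, "DEL", 6851L, sample_id = "s3")
  d <- mkSv("B", 2001L, "DEL", 6851L, sample_id = "s4")
  m <- mergeSVs(rbind(a, b, c3, d))
  expect_equal(nrow(m), 1L)
  expect_equal(m$n_carriers, 4L)
  expect_equal(m$length, 6851L)
  # different types never merge
  m2 <- mergeSVs(rbind(mkSv("B", 2000L, "DEL", 100L),
                       mkSv("B", 2000L, "INS", 100L, sample_id = "s2")))
  expect_equal(nrow(m2), 2L)
  # window boundary: 499 apart merge, 501 apart do not (brute-force pair rule)
  near <- rbind(mkSv("B", 2000L, "DEL", 60L, sample_id = "s1"),
                mkSv("B", 2499L, "DEL", 60L, sample_id = "s2"))
  far <- rbind(mkSv("B", 2000L, "DEL", 60L, sample_id = "s1"),
               mkSv("B", 2501L, "DEL", 60L, sample_id = "s2"))
  expect_equal(nrow(mergeSVs(near)), 1L)
  expect_equal(nrow(mergeSVs(far)), 2L)
})

test_that("no call is ever reported below the configured support", {
  # property over random support configurations
  set.seed(8)
  for (rep in 1:10) {
    n <- sample(3:15, 1)
    fakeOps <- lapply(seq_len(n), function(i)
      cbind(op = c(1L, 4L, 1L), len = c(1000L, 40L, 1000L)))
    s <- data.frame(read_id = sprintf("r%02d", 1:n), sample_id = "s",
                    ref_id = "A", ref_start = 1L, ref_end = 2040L,
                    strand = "+", identity = 1, aligned_fraction = 1,
                    score = 4000, assignment = "unique",
                    stringsAsFactors = FALSE)
    aln <- new("AlignmentSet", summary = s, ops = fakeOps,
               seqs = rep(strrep("A", 2000), n))
    calls <- callSVs(aln, sample_id = "s")
    if (n >= 10) expect_equal(calls$support, n)
    else expect_equal(nrow(calls), 0L)
  }
})
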