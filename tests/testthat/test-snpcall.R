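# SNP/small-indel calling: pileup construction, count/quality/frequency
# filters, homopolymer exclusion and consensus-based indels.

# synthetic pileup on the pinned A reference with counts planted at chosen
# positions (all other positions zero depth = no-call)
synPileup <- function(ref, sites) {
  L <- nchar(refSeq(ref))
  counts <- matrix(0L, L, 5L, dimnames = list(NULL, c("A", "C", "G", "T", "-")))
  for (s in sites) counts[s$pos, ] <- as.integer(s$counts)
  new("Pileup", refId = refId(ref), counts = counts,
      insertions = data.frame(read_id = character(0), pos = integer(0),
                              seq = character(0), stringsAsFactors = FALSE),
      meanQ = rep(NA_real_, L), nReads = 100L)
}

cnt <- function(A = 0, C = 0, G = 0, T = 0, del = 0) c(A, C, G, T, del)

test_that("pileup columns from error-free identical reads are single-allele", {
  refs <- fxRefs()
  run <- fxSvRun("plainA", "A", alleleEdit())
  pu <- buildPileup(run$aln, refs$A, sample = "plainA")
  d <- pileupDepth(pu)
  expect_equal(max(d), 50)
  covered <- which(d == 50)
  refCh <- strsplit(refSeq(refs$A), "")[[1]]
  idx <- cbind(covered, match(refCh[covered], c("A", "C", "G", "T", "-")))
  expect_true(all(pu@counts[idx] == 50))
  # column sums equal an independent per-read span recount
  s <- alignmentSummary(run$aln)
  span <- rep(0L, nchar(refSeq(refs$A)))
  for (i in seq_len(nrow(s)))
    span[s$ref_start[i]:s$ref_end[i]] <- span[s$ref_start[i]:s$ref_end[i]] + 1L
  expect_true(all(pileupDepth(pu) == span))
})

test_that("variant calls honour the minor-count, frequency and quality rules", {
  refs <- fxRefs()
  refCh <- strsplit(refSeq(refs$A), "")[[1]]
  cSites <- which(refCh == "C")
  pHet <- cSites[200]; pLow <- cSites[210]; pShallow <- cSites[220]
  pu <- synPileup(refs$A, list(
    list(pos = pHet, counts = cnt(C = 30, T = 70)),     # het T/C
    list(pos = pLow, counts = cnt(C = 98, T = 2)),      # low_count
    list(pos = pShallow, counts = cnt(C = 10))))        # below min depth
  calls <- callVariants(pu, refs$A)
  hit <- calls[calls$position == pHet, ]
  expect_equal(hit$zygosity, "het")
  expect_setequal(c(hit$alt, "C"), c("T", "C"))
  expect_equal(hit$filter, "pass")
  low <- calls[calls$position == pLow, ]
  expect_equal(low$filter, "low_count")
  expect_false(pShallow %in% calls$position)
})

test_that("an all-reference pileup yields no calls and hom-alt is never het", {
  refs <- fxRefs()
  refCh <- strsplit(refSeq(refs$A), "")[[1]]
  pC <- which(refCh == "C")[300]
  puRef <- synPileup(refs$A, list(list(pos = pC, counts = cnt(C = 100))))
  expect_equal(nrow(callVariants(puRef, refs$A)), 0L)
  puHom <- synPileup(refs$A, list(list(pos = pC, counts = cnt(T = 100))))
  callsHom <- callVariants(puHom, refs$A)
  expect_equal(callsHom$zygosity, "hom")
  expect_equal(callsHom$alt, "T")
})

test_that("deletion alleles need near-homozygous frequency", {
  refs <- fxRefs()
  refCh <- strsplit(refSeq(refs$A), "")[[1]]
  pC <- which(refCh == "C")[400]
  puNoise <- synPileup(refs$A, list(list(pos = pC, counts = cnt(C = 75, del = 25))))
  expect_false("pass" %in% callVariants(puNoise, refs$A)$filter)
  puHomDel <- synPileup(refs$A, list(list(pos = pC, counts = cnt(C = 6, del = 94))))
  callsDel <- callVariants(puHomDel, refs$A)
  expect_equal(callsDel$alt, "-")
  expect_equal(callsDel$filter, "pass")
})

test_that("homopolymer flagging matches a brute-force run scan", {
  refs <- fxRefs()
  set.seed(31)
  s <- paste0(rseq(300), "AAAAA", rseq(200), "GGGG", rseq(300))
  mask <- homeoplex:::homopolymerMask(s, 4L)
  ch <- strsplit(s, "")[[1]]
  brute <- integer(0)
  for (p in seq_along(ch)) {
    for (q in max(1, p - 1):min(length(ch), p + 1)) {
      lo <- q; hi <- q
      while (lo > 1 && ch[lo - 1] == ch[q]) lo <- lo - 1
      while (hi < length(ch) && ch[hi + 1] == ch[q]) hi <- hi + 1
      if (hi - lo + 1 >= 4) { brute <- c(brute, p); break }
    }
  }
  expect_setequal(mask, brute)
  # flagging behaviour on calls
  hpPos <- mask[1]
  refCh <- strsplit(refSeq(refs$A), "")[[1]]
  hpA <- which(refCh == "A" & seq_along(refCh) %in%
                 homeoplex:::homopolymerMask(refSeq(refs$A), 4L))[1]
  pu <- synPileup(refs$A, list(list(pos = hpA, counts = cnt(A = 40, T = 60))))
  calls <- homopolymerFilter(callVariants(pu, refs$A), refs$A)
  expect_true(calls$homopolymer[calls$position == hpA])
  expect_equal(calls$filter[calls$position == hpA], "homopolymer")
  # idempotence
  twice <- homopolymerFilter(calls, refs$A)
  expect_identical(calls, twice)
})

test_that("consensus/reference comparison recovers small indels", {
  refs <- fxRefs()
  s <- refSeq(refs$D)
  # identical consensus: no indels
  expect_equal(nrow(consensusIndels(s, refs$D)), 0L)
  # planted 17 bp deletion (below the SV threshold)
  del17 <- applyAllele(refs$D, knownSvEdits()[["vrn-D1r"]])
  ci <- consensusIndels(del17, refs$D)
  expect_equal(ci$type, "DEL")
  expect_equal(ci$length, 17L)
  expect_lte(abs(ci$position - 4000L), 4L)
  # single-base deletion at a pinned (clean-context) site
  del1 <- applyAllele(refs$A, alleleEdit("DEL", 5270L, 1L))
  ci1 <- consensusIndels(del1, refs$A)
  expect_equal(ci1$type, "DEL")
  expect_equal(ci1$length, 1L)
  expect_equal(ci1$position, 5270L)
})
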