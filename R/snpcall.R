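# Pileup-based SNP and single-base-deletion calling with minor-count,
# quality and homopolymer filters. Site quality is the Phred-scaled
# binomial tail probability of observing the allele count under the
# per-base error rate, thresholded at the same value (30) as the original
# workflow's caller-specific score.

.emptyCalls <- function() {
  data.frame(ref_id = character(0), position = integer(0),
             ref = character(0), alt = character(0), alt2 = character(0),
             ref_count = integer(0), alt_count = integer(0),
             alt2_count = integer(0), depth = integer(0),
             zygosity = character(0), quality = numeric(0),
             filter = character(0), stringsAsFactors = FALSE)
}

#' Call SNPs and single-base deletions from a pileup
#'
#' Sites with depth below \code{low_coverage} (default 11) are no-calls.
#' A non-reference allele (base or deletion) is a candidate when seen in at
#' least two reads at frequency >= 0.02; it passes when its count is >=
#' \code{snp_min_count} (3), its frequency >= \code{snp_het_freq} (0.20)
#' and its site quality >= \code{snp_min_qual} (30). Two qualifying
#' alleles give a heterozygous call; one qualifying allele gives a
#' heterozygous ref/alt call when the reference allele also meets the
#' frequency threshold, else a homozygous alternate call.
#'
#' @param pileup a \linkS4class{Pileup}
#' @param ref the matching \linkS4class{HomoeologReference}
#' @param params a \linkS4class{PipelineParams}
#' @return data.frame of calls (one row per variant site) with filter flags
#'   \code{pass}, \code{low_count} or \code{low_qual}
#' @export
callVariants <- function(pileup, ref, params = pipelineParams()) {
  cnt <- pileup@counts
  L <- nrow(cnt)
  depth <- rowSums(cnt)
  refCh <- seqChars(refSeq(ref))
  alpha <- c(BASES, "-")
  refIdx <- match(refCh, alpha)
  minDepth <- param(params, "low_coverage")
  minCount <- param(params, "snp_min_count")
  hetFreq <- param(params, "snp_het_freq")
  minQual <- param(params, "snp_min_qual")
  errRate <- param(params, "snp_err_rate")
  altCnt <- cnt
  altCnt[cbind(seq_len(L), refIdx)] <- 0L
  altMax <- do.call(pmax, as.data.frame(altCnt))
  cand <- which(depth >= minDepth & altMax >= 2L & altMax / pmax(depth, 1) >= 0.02)
  if (!length(cand)) return(.emptyCalls())
  rows <- vector("list", length(cand))
  delFreq <- param(params, "snp_del_min_freq")
  for (k in seq_along(cand)) {
    p <- cand[k]
    d <- depth[p]
    ac <- altCnt[p, ]
    o <- order(-ac)
    a1 <- o[1]; a2 <- o[2]
    # nanopore per-base deletion noise stacks at homopolymer-flank
    # positions; deletion alleles therefore need a near-homozygous
    # frequency, base alleles the ordinary het threshold
    f1 <- if (a1 == 5L) max(hetFreq, delFreq) else hetFreq
    f2 <- if (a2 == 5L) max(hetFreq, delFreq) else hetFreq
    q1 <- phredQual(ac[a1], d, errRate)
    pass1 <- ac[a1] >= minCount && ac[a1] / d >= f1 && q1 >= minQual
    has2 <- ac[a2] >= minCount && ac[a2] / d >= f2 &&
      phredQual(ac[a2], d, errRate) >= minQual
    refC <- cnt[p, refIdx[p]]
    refQualifies <- refC / d >= hetFreq
    zyg <- if (pass1 && has2) "het"
           else if (pass1 && refQualifies) "het"
           else if (pass1) "hom" else NA_character_
    filt <- if (pass1) "pass"
            else if (ac[a1] < minCount) "low_count"
            else if (ac[a1] / d < hetFreq) "low_count"
            else "low_qual"
    rows[[k]] <- data.frame(
      ref_id = pileup@refId, position = p, ref = refCh[p],
      alt = alpha[a1], alt2 = if (pass1 && has2) alpha[a2] else NA_character_,
      ref_count = as.integer(refC), alt_count = as.integer(ac[a1]),
      alt2_count = if (pass1 && has2) as.integer(ac[a2]) else NA_integer_,
      depth = as.integer(d), zygosity = zyg, quality = round(q1, 1),
      filter = filt, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Flag calls in homopolymeric context
#'
#' A call whose position lies inside, or immediately adjacent to, a
#' single-base run of at least \code{homopolymer_run} bases (default 4) is
#' flagged \code{homopolymer}; flagged calls are excluded from downstream
#' haplotype and grouping steps. The flagging is idempotent.
#'
#' @param calls call data.frame from \code{\link{callVariants}}
#' @param ref the \linkS4class{HomoeologReference}
#' @param params a \linkS4class{PipelineParams}
#' @return calls with a logical \code{homopolymer} column and updated
#'   \code{filter}
#' @export
homopolymerFilter <- function(calls, ref, params = pipelineParams()) {
  mask <- homopolymerMask(refSeq(ref), param(params, "homopolymer_run"))
  hp <- calls$position %in% mask
  calls$homopolymer <- hp
  calls$filter[hp & calls$filter == "pass"] <- "homopolymer"
  calls
}

#' Passing (analysis-ready) variant calls
#'
#' @param calls a call data.frame after \code{\link{homopolymerFilter}}
#' @return subset with filter == "pass"
#' @export
passCalls <- function(calls) calls[calls$filter == "pass", , drop = FALSE]
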