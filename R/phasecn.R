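# Read-backed haplotype phasing over heterozygous sites and the
# haplotype-count / allele-dosage / dosage-cluster copy-number classifier.

#' Per-read alleles at reference sites
#'
#' Extracts, for each uniquely assigned read, the base carried at each of
#' the given reference positions ("-" at deletions, NA when the read does
#' not cover the site).
#'
#' @param aln an \linkS4class{AlignmentSet}
#' @param sites 1-based reference positions
#' @param refIdUse restrict to reads on this reference (optional)
#' @return character matrix, reads x sites
#' @export
readAllelesAt <- function(aln, sites, refIdUse = NULL) {
  s <- alignmentSummary(aln)
  keep <- s$assignment == "unique"
  if (!is.null(refIdUse)) keep <- keep & s$ref_id == refIdUse
  idx <- which(keep)
  ops <- alignmentOps(aln)
  out <- matrix(NA_character_, length(idx), length(sites),
                dimnames = list(s$read_id[idx], as.character(sites)))
  for (r in seq_along(idx)) {
    i <- idx[r]
    ex <- .expandOps(ops[[i]], s$ref_start[i], NULL)
    ch <- seqChars(aln@seqs[i])
    hit <- match(sites, ex$refPos)  # first alignment column at the site
    for (k in seq_along(sites)) {
      j <- hit[k]
      if (is.na(j)) next
      out[r, k] <- if (ex$opv[j] == OP_D) "-" else ch[ex$readPos[j]]
    }
  }
  out
}

#' Phase haplotypes from reads spanning heterozygous sites
#'
#' Every read spanning all sites contributes one allele-vector observation;
#' vectors supported by at least \code{hap_min_support} reads (default 10)
#' become haplotypes. Reads carrying an allele outside the called allele
#' set at any site are counted ambiguous. With a single site the
#' haplotypes degenerate to the alleles themselves.
#'
#' @param x an \linkS4class{AlignmentSet} or a character matrix of
#'   per-read alleles (reads x sites, NA = not covered)
#' @param sites 1-based site positions (required with an AlignmentSet)
#' @param alleles optional list (per site) of called alleles; reads with
#'   other alleles are ambiguous
#' @param params a \linkS4class{PipelineParams}
#' @param refIdUse reference restriction passed to
#'   \code{\link{readAllelesAt}}
#' @return a \linkS4class{HaplotypeSet}; status "unphaseable" when no read
#'   spans all sites
#' @export
phaseHaplotypes <- function(x, sites = NULL, alleles = NULL,
                            params = pipelineParams(), refIdUse = NULL) {
  if (is(x, "AlignmentSet")) {
    if (is.null(sites)) stop("sites required")
    m <- readAllelesAt(x, sites, refIdUse)
  } else {
    m <- x
    if (is.null(sites)) sites <- seq_len(ncol(m))
  }
  minSupp <- param(params, "hap_min_support")
  span <- !apply(is.na(m), 1, any)
  mS <- m[span, , drop = FALSE]
  nSpan <- nrow(mS)
  if (nSpan == 0)
    return(new("HaplotypeSet", sites = as.integer(sites),
               haplotypes = data.frame(haplotype = character(0),
                                       support = integer(0)),
               ambiguous = 0L, spanning = 0L, status = "unphaseable"))
  ok <- rep(TRUE, nSpan)
  if (!is.null(alleles)) {
    for (k in seq_along(sites))
      ok <- ok & mS[, k] %in% alleles[[k]]
  }
  vec <- apply(mS[ok, , drop = FALSE], 1, paste, collapse = "-")
  tb <- sort(table(vec), decreasing = TRUE)
  keep <- tb >= minSupp
  hap <- data.frame(haplotype = names(tb)[keep],
                    support = as.integer(tb[keep]),
                    stringsAsFactors = FALSE)
  new("HaplotypeSet", sites = as.integer(sites), haplotypes = hap,
      ambiguous = as.integer(sum(!ok)), spanning = as.integer(nSpan),
      status = "phased")
}

#' Allele dosage at a heterozygous site
#'
#' Computes the alternate-allele read frequency with a Wilson 95 percent
#' confidence interval and a two-sided binomial test against the balanced
#' dosage 0.5. Dosage is unreliable below \code{dosage_min_depth} informative
#' reads (default 30).
#'
#' @param pileup a \linkS4class{Pileup}
#' @param site 1-based position
#' @param refAllele,altAllele the two called alleles ("-" for deletion)
#' @param params a \linkS4class{PipelineParams}
#' @return list: frequency, ci (length-2), p_value, depth, reliable
#' @export
alleleDosage <- function(pileup, site, refAllele, altAllele,
                         params = pipelineParams()) {
  alpha <- c(BASES, "-")
  rc <- pileup@counts[site, match(refAllele, alpha)]
  ac <- pileup@counts[site, match(altAllele, alpha)]
  d <- rc + ac
  reliable <- d >= param(params, "dosage_min_depth")
  if (d == 0)
    return(list(frequency = NA_real_, ci = c(NA_real_, NA_real_),
                p_value = NA_real_, depth = 0L, reliable = FALSE))
  freq <- ac / d
  ci <- wilsonCI(ac, d)
  pv <- binom.test(ac, d, p = 0.5)$p.value
  list(frequency = freq, ci = unname(ci), p_value = pv,
       depth = as.integer(d), reliable = reliable)
}

#' Dosage-cluster classification (balanced vs skewed)
#'
#' The skewed cluster (the three-copy analogue, about 70 percent alternate
#' reads) requires the confidence interval to exclude 0.5 and the
#' frequency to be at least 0.6; the balanced cluster (the two-copy
#' analogue, about 50 percent) requires the interval to contain 0.5 or the
#' frequency to lie in [0.4, 0.6]. Anything else is indeterminate, never
#' silently coerced.
#'
#' @param frequency alt-allele frequency
#' @param ci length-2 confidence interval
#' @return "balanced", "skewed" or "indeterminate"
#' @export
dosageCluster <- function(frequency, ci) {
  if (is.na(frequency)) return("indeterminate")
  excl <- ci[1] > 0.5 || ci[2] < 0.5
  if (excl && frequency >= 0.6) return("skewed")
  if (!excl || (frequency >= 0.4 && frequency <= 0.6)) return("balanced")
  "indeterminate"
}

#' Copy-number classification from haplotypes and dosage
#'
#' Decision rule: homozygous at the dosage site with one haplotype = 1
#' copy; two haplotypes with balanced dosage = 2; two haplotypes with
#' skewed dosage = 3 (two copies carry the major allele); four haplotypes
#' = 4. In all other configurations the copy number equals the haplotype
#' count (the phased minimum) with the evidence noting the uncorroborated
#' dosage; contradictory evidence is flagged but never reduces the count
#' below the haplotype minimum.
#'
#' @param hapSet a \linkS4class{HaplotypeSet}
#' @param dosage result of \code{\link{alleleDosage}} (optional for
#'   homozygous samples)
#' @param zygosity "het" or "hom" at the dosage site
#' @param site dosage site position
#' @return a \linkS4class{CopyNumberEstimate}
#' @export
copyNumberCall <- function(hapSet, dosage = NULL, zygosity = c("het", "hom"),
                           site = NA_integer_) {
  zygosity <- match.arg(zygosity)
  nh <- nHaplotypes(hapSet)
  cl <- if (!is.null(dosage)) dosageCluster(dosage$frequency, dosage$ci)
        else "indeterminate"
  freq <- if (!is.null(dosage)) dosage$frequency else NA_real_
  ci <- if (!is.null(dosage)) dosage$ci else c(NA_real_, NA_real_)
  if (zygosity == "hom" && nh <= 1) {
    cn <- 1L; ev <- "homozygous dosage site, single haplotype"
  } else if (nh == 2 && cl == "balanced") {
    cn <- 2L; ev <- "2 haplotypes, balanced dosage"
  } else if (nh == 2 && cl == "skewed") {
    cn <- 3L; ev <- "2 haplotypes, skewed dosage (major allele on 2 copies)"
  } else if (nh == 4) {
    cn <- 4L
    ev <- if (cl == "skewed")
      "4 haplotypes; skewed dosage contradicts the 4-copy model (flagged)"
    else "4 haplotypes"
  } else {
    cn <- max(nh, 1L)
    ev <- sprintf("%d haplotypes; dosage %s (uncorroborated)", nh, cl)
  }
  new("CopyNumberEstimate", nHaplotypes = as.integer(nh),
      dosageSite = as.integer(site), frequency = freq, ci = ci,
      cluster = cl, copyNumber = as.integer(cn), evidence = ev)
}

#' Allele dosage by local realignment of spanning reads
#'
#' Raw pileup dosage is reference-biased with indel-noisy long reads:
#' a read carrying the alternate allele can have its mismatch absorbed
#' into a nearby indel representation, dropping it from the alternate
#' count. Here every read spanning the site is locally re-aligned
#' (window of \code{flank} bases) against the two allele contexts and
#' assigned to the better-scoring allele; ties are dropped.
#'
#' @param aln an \linkS4class{AlignmentSet}
#' @param ref the \linkS4class{HomoeologReference}
#' @param site 1-based position
#' @param refAllele,altAllele the two called alleles (single bases)
#' @param params a \linkS4class{PipelineParams}
#' @param flank context half-width (default 20)
#' @return as \code{\link{alleleDosage}}: frequency, ci, p_value, depth,
#'   reliable
#' @export
dosageFromAlignments <- function(aln, ref, site, refAllele, altAllele,
                                 params = pipelineParams(), flank = 20L) {
  refStr <- refSeq(ref)
  lo <- max(1L, site - flank); hi <- min(nchar(refStr), site + flank)
  ctxRef <- substr(refStr, lo, hi)
  at <- site - lo + 1L
  ctxAlt <- paste0(substr(ctxRef, 1L, at - 1L), altAllele,
                   substr(ctxRef, at + 1L, nchar(ctxRef)))
  s <- alignmentSummary(aln)
  idx <- which(s$assignment == "unique" & s$ref_id == refId(ref) &
                 s$ref_start <= lo & s$ref_end >= hi)
  ops <- alignmentOps(aln)
  mm <- param(params, "aln_match"); mx <- param(params, "aln_mismatch")
  go <- param(params, "aln_gap_open"); ge <- param(params, "aln_gap_ext")
  scoreOps <- function(r) {
    op <- r$op; len <- r$len
    ind <- op == OP_I | op == OP_D
    sum(mm * len[op == OP_M]) - sum(mx * len[op == OP_X]) -
      sum(go + ge * len[ind])
  }
  nRef <- 0L; nAlt <- 0L
  for (i in idx) {
    ex <- .expandOps(ops[[i]], s$ref_start[i], NULL)
    rp <- range(ex$readPos[ex$refPos >= lo & ex$refPos <= hi &
                             ex$opv != OP_D])
    if (!all(is.finite(rp))) next
    sub <- substr(aln@seqs[i], rp[1], rp[2])
    if (!nzchar(sub)) next
    a <- cpp_nw_ops(sub, ctxRef, mm, mx, go, ge)
    b <- cpp_nw_ops(sub, ctxAlt, mm, mx, go, ge)
    d <- scoreOps(b) - scoreOps(a)
    if (d > 0) nAlt <- nAlt + 1L else if (d < 0) nRef <- nRef + 1L
  }
  dTot <- nRef + nAlt
  reliable <- dTot >= param(params, "dosage_min_depth")
  if (dTot == 0)
    return(list(frequency = NA_real_, ci = c(NA_real_, NA_real_),
                p_value = NA_real_, depth = 0L, reliable = FALSE))
  list(frequency = nAlt / dTot, ci = unname(wilsonCI(nAlt, dTot)),
       p_value = binom.test(nAlt, dTot, p = 0.5)$p.value,
       depth = as.integer(dTot), reliable = reliable)
}
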