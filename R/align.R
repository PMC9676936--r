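# SV-tolerant two-pass alignment: coarse k-mer anchor chaining, then
# gap-aware refinement with affine dynamic programming between anchors.
# Long indels between anchors stay single operations, which the SV caller
# depends on. Op codes: 1 = M, 2 = X, 3 = I, 4 = D, 5 = S (soft clip).

OP_M <- 1L; OP_X <- 2L; OP_I <- 3L; OP_D <- 4L; OP_S <- 5L

.kmerCodes <- function(ch, k) {
  v <- match(ch, BASES) - 1L
  n <- length(v)
  if (n < k) return(numeric(0))
  code <- numeric(n - k + 1L)
  for (j in seq_len(k)) code <- code * 4 + v[j:(n - k + j)]
  code
}

# reference k-mer index: list(codeChar -> positions), built once per reference
.refIndex <- function(refSeqStr, k) {
  ch <- seqChars(refSeqStr)
  codes <- .kmerCodes(ch, k)
  idx <- split(seq_along(codes), codes)
  occ <- lengths(idx)
  idx <- idx[occ <= 10L]  # drop hyper-repetitive seeds
  list(index = idx, k = k, n = nchar(refSeqStr))
}

# merged co-diagonal anchors between a query and an indexed reference
.anchors <- function(qch, ridx) {
  k <- ridx$k
  qcodes <- .kmerCodes(qch, k)
  if (!length(qcodes)) return(NULL)
  hit <- ridx$index[as.character(qcodes)]
  names(hit) <- NULL
  nh <- lengths(hit)
  keep <- nh > 0
  if (!any(keep)) return(NULL)
  qp <- rep(seq_along(qcodes)[keep], nh[keep])
  rp <- unlist(hit[keep], use.names = FALSE)
  diag <- rp - qp
  o <- order(diag, qp)
  qp <- qp[o]; rp <- rp[o]; diag <- diag[o]
  newRun <- c(TRUE, !(diff(diag) == 0L & diff(qp) == 1L))
  grp <- cumsum(newRun)
  qs <- qp[newRun]
  rs <- rp[newRun]
  cnt <- tabulate(grp)
  data.frame(q = qs, r = rs, len = cnt + k - 1L)
}

.chainScore <- function(anch) {
  if (is.null(anch) || nrow(anch) == 0) return(list(score = -Inf, chain = NULL))
  sel <- cpp_chain(anch$q - 1L, anch$r - 1L, anch$len, 0.05, 1)
  ch <- anch[sel, , drop = FALSE]
  # trim chance overlaps against the predecessor so anchors are disjoint
  if (nrow(ch) > 1) {
    for (t in 2:nrow(ch)) {
      o <- max(0L, ch$q[t - 1L] + ch$len[t - 1L] - ch$q[t],
               ch$r[t - 1L] + ch$len[t - 1L] - ch$r[t])
      if (o > 0L) {
        ch$q[t] <- ch$q[t] + o; ch$r[t] <- ch$r[t] + o
        ch$len[t] <- ch$len[t] - o
      }
    }
    ch <- ch[ch$len > 0L, , drop = FALSE]
  }
  list(score = sum(ch$len), chain = ch)
}

#' Align one sequence to one reference with the seed-chain aligner
#'
#' @param query query sequence (character)
#' @param refStr reference sequence (character)
#' @param params a \linkS4class{PipelineParams}
#' @param ridx optional prebuilt reference index
#' @return list with run-length \code{ops} (matrix op/len), \code{ref_start}
#'   and \code{ref_end} (1-based inclusive), counts of matches, mismatches,
#'   insertions, deletions and clips, \code{identity}, \code{aligned_fraction}
#'   and \code{score}; NULL when no anchor chain exists
#' @export
seedChainAlign <- function(query, refStr, params = pipelineParams(),
                           ridx = NULL) {
  if (is.null(ridx)) ridx <- .refIndex(refStr, param(params, "aln_k"))
  qch <- seqChars(query)
  cs <- .chainScore(.anchors(qch, ridx))
  if (is.null(cs$chain)) return(NULL)
  .refineChain(query, refStr, cs$chain, params)
}

.refineChain <- function(query, refStr, chain, params) {
  r <- cpp_refine(query, refStr,
                  chain$q - 1L, chain$r - 1L, chain$len,
                  param(params, "aln_match"), param(params, "aln_mismatch"),
                  param(params, "aln_gap_open"), param(params, "aln_gap_ext"),
                  param(params, "aln_max_dp"))
  # gap-compressed identity: a contiguous indel counts one column, so reads
  # spanning multi-kb SVs are not penalised per gap base (cf. long-read
  # mapper identity conventions)
  indel <- r$op == OP_I | r$op == OP_D
  nIndelRuns <- sum(indel)
  cols <- r$matches + r$mismatches + nIndelRuns
  # SV-tolerant score: gap penalties are capped at the SV length threshold
  # so reads spanning multi-kb indels still outscore alignments to the
  # wrong homoeolog
  gapO <- param(params, "aln_gap_open"); gapE <- param(params, "aln_gap_ext")
  gapPen <- sum(pmin(gapO + gapE * r$len[indel], gapO + gapE * 30))
  score <- param(params, "aln_match") * r$matches -
    param(params, "aln_mismatch") * r$mismatches - gapPen
  list(ops = cbind(op = r$op, len = r$len),
       ref_start = r$ref_start + 1L, ref_end = r$ref_end,
       matches = r$matches, mismatches = r$mismatches,
       ins = r$ins, del = r$del, clip = r$clip,
       identity = if (cols > 0) r$matches / cols else 0,
       aligned_fraction = (r$matches + r$mismatches + r$ins) / nchar(query),
       score = score)
}

#' Global pairwise identity of two sequences
#'
#' Identity is matches divided by alignment columns (gap columns included;
#' soft-clipped bases count as columns), computed with the seed-chain
#' aligner.
#'
#' @param a,b sequences (character)
#' @param params a \linkS4class{PipelineParams}
#' @return identity in [0, 1]
#' @export
globalIdentity <- function(a, b, params = pipelineParams()) {
  al <- seedChainAlign(a, b, params)
  if (is.null(al)) return(0)
  cols <- al$matches + al$mismatches + al$ins + al$del + al$clip +
    (al$ref_start - 1) + (nchar(b) - al$ref_end)
  al$matches / cols
}

#' Align a read against all homoeolog references
#'
#' Both orientations are chained against every reference; the best chain
#' per reference is refined (others only when their chain score is within
#' the ambiguity zone of the best, or when \code{refineAll}). Candidate
#' scores for unrefined references are the chain scores rescaled to match
#' units.
#'
#' @param read read sequence (character)
#' @param refs named list of \linkS4class{HomoeologReference}
#' @param params a \linkS4class{PipelineParams}
#' @param indices optional prebuilt per-reference k-mer indices
#' @param refineAll refine every reference (slower; full identity per
#'   candidate)
#' @return data.frame of candidates (one row per reference) with attribute
#'   \code{"alignments"}: list of refined alignment lists (NULL when not
#'   refined)
#' @export
alignToReferences <- function(read, refs, params = pipelineParams(),
                              indices = NULL, refineAll = FALSE) {
  k <- param(params, "aln_k")
  if (nchar(read) < k) stop("read shorter than the seed length")
  if (is.null(indices))
    indices <- lapply(refs, function(r) .refIndex(refSeq(r), k))
  rcRead <- revComp(read)
  qf <- seqChars(read); qr <- seqChars(rcRead)
  chains <- lapply(names(refs), function(id) {
    f <- .chainScore(.anchors(qf, indices[[id]]))
    r <- .chainScore(.anchors(qr, indices[[id]]))
    if (f$score >= r$score) c(f, strand = "+") else c(r, strand = "-")
  })
  names(chains) <- names(refs)
  chainScores <- vapply(chains, function(x) x$score, 0)
  best <- which.max(chainScores)
  margin2 <- 2 * param(params, "uniq_margin")
  out <- vector("list", length(refs))
  names(out) <- names(refs)
  for (i in seq_along(refs)) {
    doRefine <- refineAll || i == best ||
      (is.finite(chainScores[i]) &&
         2 * (chainScores[best] - chainScores[i]) < margin2)
    if (doRefine && !is.null(chains[[i]]$chain)) {
      q <- if (chains[[i]]$strand == "+") read else rcRead
      out[[i]] <- .refineChain(q, refSeq(refs[[i]]), chains[[i]]$chain, params)
      out[[i]]$strand <- chains[[i]]$strand
    }
  }
  cand <- data.frame(
    ref_id = names(refs),
    strand = vapply(chains, function(x) x$strand, ""),
    chain_score = unname(chainScores),
    score = vapply(seq_along(refs), function(i)
      if (!is.null(out[[i]])) out[[i]]$score else 2 * chainScores[i], 0),
    identity = vapply(seq_along(refs), function(i)
      if (!is.null(out[[i]])) out[[i]]$identity else NA_real_, 0),
    aligned_fraction = vapply(seq_along(refs), function(i)
      if (!is.null(out[[i]])) out[[i]]$aligned_fraction else NA_real_, 0),
    stringsAsFactors = FALSE)
  attr(cand, "alignments") <- out
  cand
}

#' Assign a read to a homoeolog from its reference candidates
#'
#' A read is unaligned when the best identity is below \code{min_identity}
#' or the aligned fraction below \code{min_aligned_fraction}; ambiguous
#' when the margin between best and second-best alignment score is below
#' the uniqueness margin (the mapping-quality analogue); otherwise uniquely
#' assigned to the best reference.
#'
#' @param cand candidate table from \code{\link{alignToReferences}}
#' @param params a \linkS4class{PipelineParams}
#' @return list: \code{assignment} ("unique", "ambiguous", "unaligned"),
#'   \code{ref_id}, and the refined \code{alignment} for the best reference
#' @export
assignHomoeolog <- function(cand, params = pipelineParams()) {
  aln <- attr(cand, "alignments")
  o <- order(-cand$score)
  b <- o[1]
  margin <- if (length(o) > 1) cand$score[b] - cand$score[o[2]] else Inf
  bestAln <- aln[[b]]
  if (is.null(bestAln) ||
      bestAln$identity < param(params, "min_identity") ||
      bestAln$aligned_fraction < param(params, "min_aligned_fraction")) {
    return(list(assignment = "unaligned", ref_id = NA_character_,
                alignment = bestAln))
  }
  if (margin < param(params, "uniq_margin"))
    return(list(assignment = "ambiguous", ref_id = cand$ref_id[b],
                alignment = bestAln))
  list(assignment = "unique", ref_id = cand$ref_id[b], alignment = bestAln)
}

#' Align a set of reads to the homoeolog references
#'
#' @param reads named character vector, \link[Biostrings]{DNAStringSet} or
#'   \linkS4class{SimPanel}
#' @param refs named list of \linkS4class{HomoeologReference}
#' @param params a \linkS4class{PipelineParams}
#' @param sample_ids optional per-read sample labels carried into the summary
#' @return an \linkS4class{AlignmentSet}
#' @export
alignPanel <- function(reads, refs, params = pipelineParams(),
                       sample_ids = NULL) {
  if (is(reads, "SimPanel")) {
    if (is.null(sample_ids)) sample_ids <- panelTruth(reads)$cultivar
    reads <- panelReads(reads)
  }
  if (is(reads, "DNAStringSet")) reads <- as.character(reads)
  if (is.null(names(reads))) names(reads) <- sprintf("read%06d", seq_along(reads))
  if (is.null(sample_ids)) sample_ids <- rep(NA_character_, length(reads))
  k <- param(params, "aln_k")
  indices <- lapply(refs, function(r) .refIndex(refSeq(r), k))
  n <- length(reads)
  ops <- vector("list", n)
  seqs <- character(n)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    cand <- alignToReferences(reads[[i]], refs, params, indices)
    asg <- assignHomoeolog(cand, params)
    al <- asg$alignment
    if (is.null(al)) {
      rows[[i]] <- data.frame(
        read_id = names(reads)[i], sample_id = sample_ids[i],
        ref_id = NA_character_, ref_start = NA_integer_, ref_end = NA_integer_,
        strand = NA_character_, identity = NA_real_,
        aligned_fraction = NA_real_, score = NA_real_,
        assignment = "unaligned", stringsAsFactors = FALSE)
      next
    }
    ops[[i]] <- al$ops
    seqs[i] <- if (al$strand == "+") reads[[i]] else revComp(reads[[i]])
    rows[[i]] <- data.frame(
      read_id = names(reads)[i], sample_id = sample_ids[i],
      ref_id = asg$ref_id, ref_start = al$ref_start, ref_end = al$ref_end,
      strand = al$strand, identity = al$identity,
      aligned_fraction = al$aligned_fraction, score = al$score,
      assignment = asg$assignment, stringsAsFactors = FALSE)
  }
  new("AlignmentSet", summary = do.call(rbind, rows), ops = ops, seqs = seqs)
}

#' Per-sample, per-homoeolog coverage statistics
#'
#' Depth is aligned reference span divided by reference length. The
#' coefficient of variation (sd/mean across samples) is reported per
#' homoeolog, along with pairwise per-sample depth ratios and low-coverage
#' flags.
#'
#' @param aln an \linkS4class{AlignmentSet} (unique assignments are used)
#' @param refs named list of \linkS4class{HomoeologReference}
#' @param lowCoverage depth threshold flagging outliers (default 11)
#' @return list with \code{depth} (samples x homoeologs), \code{cv} (per
#'   homoeolog), \code{ratios} (per-sample pairwise ratios) and
#'   \code{low_coverage} flags
#' @export
coverageStats <- function(aln, refs, lowCoverage = 11) {
  s <- alignmentSummary(aln)
  s <- s[s$assignment == "unique", , drop = FALSE]
  if (nrow(s) == 0) stop("no uniquely assigned reads")
  samples <- sort(unique(s$sample_id))
  homs <- names(refs)
  depth <- matrix(0, length(samples), length(homs),
                  dimnames = list(samples, homs))
  span <- s$ref_end - s$ref_start + 1
  for (i in seq_len(nrow(s)))
    depth[s$sample_id[i], s$ref_id[i]] <-
      depth[s$sample_id[i], s$ref_id[i]] + span[i]
  for (h in homs) depth[, h] <- depth[, h] / nchar(refSeq(refs[[h]]))
  cv <- apply(depth, 2, function(x) if (mean(x) > 0) sd(x) / mean(x) else NA_real_)
  pairs <- if (length(homs) >= 3)
    list(c(1, 2), c(2, 3), c(1, 3)) else list(c(1, 2))
  ratios <- do.call(cbind, lapply(pairs, function(p) {
    r <- ifelse(depth[, p[2]] > 0, depth[, p[1]] / depth[, p[2]], NA_real_)
    r
  }))
  colnames(ratios) <- vapply(pairs, function(p)
    paste0(homs[p[1]], "/", homs[p[2]]), "")
  list(depth = depth, cv = cv, ratios = ratios,
       low_coverage = depth < lowCoverage)
}
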