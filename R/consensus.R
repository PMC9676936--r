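# Pileup construction and reference-guided consensus.

#' Pileup over a homoeolog reference
#'
#' Per reference position: counts of A/C/G/T and deletion among uniquely
#' assigned reads, plus recorded insertion events (position = reference
#' base after which the insertion occurs). Soft-clipped bases are ignored.
#'
#' @slot refId reference label
#' @slot counts L x 5 count matrix (columns A, C, G, T, -)
#' @slot insertions data.frame read_id / pos / seq
#' @slot meanQ per-position mean of per-read mean quality (NA when
#'   qualities were not supplied)
#' @export
setClass("Pileup",
  representation(refId = "character", counts = "matrix",
                 insertions = "data.frame", meanQ = "numeric",
                 nReads = "integer"))

setMethod("show", "Pileup", function(object) {
  d <- pileupDepth(object)
  cat("Pileup on", object@refId, "-", nrow(object@counts), "positions,",
      "mean depth", round(mean(d), 1), "\n")
})

#' @describeIn Pileup total depth per reference position (deletion-spanning
#'   reads included)
#' @param x a Pileup
#' @export
pileupDepth <- function(x) rowSums(x@counts)

# expand one read's run-length ops into per-base vectors
.expandOps <- function(ops, refStart, alignedSeq) {
  opv <- rep(ops[, 1], ops[, 2])
  consRef <- opv == OP_M | opv == OP_X | opv == OP_D
  consRead <- opv != OP_D
  refPos <- refStart - 1L + cumsum(consRef)
  readPos <- cumsum(consRead)
  list(opv = opv, refPos = refPos, readPos = readPos)
}

#' Build a pileup from an alignment set
#'
#' @param aln an \linkS4class{AlignmentSet}
#' @param ref the \linkS4class{HomoeologReference} aligned against
#' @param sample restrict to one sample id (optional)
#' @param quals optional named per-read Phred+33 quality strings; enables
#'   the per-position mean-quality track
#' @return a \linkS4class{Pileup}
#' @export
buildPileup <- function(aln, ref, sample = NULL, quals = NULL) {
  s <- alignmentSummary(aln)
  keep <- s$assignment == "unique" & s$ref_id == refId(ref)
  if (!is.null(sample)) keep <- keep & s$sample_id %in% sample
  idx <- which(keep)
  L <- nchar(refSeq(ref))
  counts <- matrix(0L, L, 5L, dimnames = list(NULL, c(BASES, "-")))
  insRows <- list()
  qSum <- numeric(L); qN <- numeric(L)
  ops <- alignmentOps(aln)
  for (i in idx) {
    op <- ops[[i]]
    ex <- .expandOps(op, s$ref_start[i], NULL)
    ch <- seqChars(aln@seqs[i])
    mx <- ex$opv == OP_M | ex$opv == OP_X
    del <- ex$opv == OP_D
    pos <- ex$refPos[mx]
    bi <- match(ch[ex$readPos[mx]], BASES)
    ok <- !is.na(bi) & pos >= 1L & pos <= L
    ix <- (bi[ok] - 1L) * L + pos[ok]
    dpos <- ex$refPos[del]
    dok <- dpos >= 1L & dpos <= L
    ix <- c(ix, 4L * L + dpos[dok])
    tb <- tabulate(ix, nbins = 5L * L)
    counts <- counts + matrix(tb, L, 5L)
    # insertion runs
    iRuns <- which(op[, 1] == OP_I)
    if (length(iRuns)) {
      refC <- cumsum(c(0L, (op[, 2] * (op[, 1] %in% c(OP_M, OP_X, OP_D)))))
      readC <- cumsum(c(0L, (op[, 2] * (op[, 1] != OP_D))))
      for (j in iRuns) {
        p <- s$ref_start[i] - 1L + refC[j]
        insRows[[length(insRows) + 1L]] <- data.frame(
          read_id = s$read_id[i], pos = p,
          seq = substr(aln@seqs[i], readC[j] + 1L, readC[j] + op[j, 2]),
          stringsAsFactors = FALSE)
      }
    }
    if (!is.null(quals)) {
      qs <- quals[[s$read_id[i]]]
      if (!is.null(qs)) {
        mq <- meanQscore(utf8ToInt(as.character(qs)) - 33L)
        cov <- unique(ex$refPos[ex$refPos >= 1L & ex$refPos <= L])
        qSum[cov] <- qSum[cov] + mq
        qN[cov] <- qN[cov] + 1
      }
    }
  }
  insertions <- if (length(insRows)) do.call(rbind, insRows) else
    data.frame(read_id = character(0), pos = integer(0), seq = character(0),
               stringsAsFactors = FALSE)
  meanQ <- ifelse(qN > 0, qSum / pmax(qN, 1), NA_real_)
  new("Pileup", refId = refId(ref), counts = counts, insertions = insertions,
      meanQ = meanQ, nReads = length(idx))
}

#' Reference-guided consensus by column-wise majority vote
#'
#' Gap columns participate in the vote, so deletions and insertions carried
#' by a majority of reads propagate to the consensus; ties are broken
#' toward the reference base (conservative, deterministic). Positions with
#' no coverage emit the reference base at depth 0. Fails explicitly when
#' fewer than \code{minReads} reads support the sample/homoeolog.
#'
#' @param pileup a \linkS4class{Pileup}
#' @param ref the matching \linkS4class{HomoeologReference}
#' @param minReads minimum read support (default 3)
#' @return list: \code{seq} (consensus), \code{depth} (per consensus base),
#'   \code{nReads}
#' @export
referenceGuidedConsensus <- function(pileup, ref, minReads = 3L) {
  depth <- pileupDepth(pileup)
  nReads <- pileup@nReads
  if (nReads < minReads)
    stop(structure(class = c("lowCoverageError", "error", "condition"),
                   list(message = sprintf(
                     "insufficient coverage: %d reads < %d required",
                     as.integer(nReads), as.integer(minReads)),
                     call = sys.call())))
  L <- nrow(pileup@counts)
  refCh <- seqChars(refSeq(ref))
  alpha <- c(BASES, "-")
  refIdx <- match(refCh, alpha)
  cnt <- pileup@counts
  # majority with ties toward the reference: add half a vote to the ref base
  tie <- cnt + 0
  tie[cbind(seq_len(L), refIdx)] <- tie[cbind(seq_len(L), refIdx)] + 0.5
  maj <- max.col(tie, ties.method = "first")
  maj[depth == 0] <- refIdx[depth == 0]
  # insertion consensus: inserted after pos when supported by a majority of
  # spanning reads; modal sequence, ties to the lexicographically smallest
  insAfter <- rep(NA_character_, L)
  if (nrow(pileup@insertions)) {
    byPos <- split(pileup@insertions$seq, pileup@insertions$pos)
    for (p in names(byPos)) {
      pp <- as.integer(p)
      if (pp < 1L || pp > L) next
      supp <- length(byPos[[p]])
      if (supp > depth[pp] / 2) {
        tb <- sort(table(byPos[[p]]), decreasing = TRUE)
        top <- names(tb)[tb == max(tb)]
        insAfter[pp] <- sort(top)[1]
      }
    }
  }
  keep <- maj != 5L
  pieces <- character(L)
  for (p in seq_len(L)) {
    b <- if (keep[p]) alpha[maj[p]] else ""
    if (!is.na(insAfter[p])) b <- paste0(b, insAfter[p])
    pieces[p] <- b
  }
  seqOut <- paste(pieces, collapse = "")
  nc <- nchar(pieces)
  outDepth <- rep(depth, times = nc)
  list(seq = seqOut, depth = outDepth, nReads = nReads)
}

#' Small indels from a consensus/reference comparison
#'
#' Globally aligns a consensus sequence to its reference and reports gap
#' runs of length in [minLen, maxLen] (below the SV threshold) as small
#' indel calls in reference coordinates.
#'
#' @param consensus consensus sequence (character)
#' @param ref \linkS4class{HomoeologReference} or character
#' @param minLen,maxLen reported gap-length range (defaults 1 and 29)
#' @param params a \linkS4class{PipelineParams}
#' @return data.frame: ref_id, position, type (INS/DEL), length, alt
#' @export
consensusIndels <- function(consensus, ref, minLen = 1L, maxLen = 29L,
                            params = pipelineParams()) {
  refStr <- if (is(ref, "HomoeologReference")) refSeq(ref) else ref
  rid <- if (is(ref, "HomoeologReference")) refId(ref) else NA_character_
  if (is.null(consensus) || !nzchar(consensus))
    return(data.frame(ref_id = character(0), position = integer(0),
                      type = character(0), length = integer(0),
                      alt = character(0), stringsAsFactors = FALSE))
  al <- seedChainAlign(consensus, refStr, params)
  if (is.null(al)) stop("consensus could not be aligned to the reference")
  op <- al$ops
  refC <- cumsum(c(0L, op[, 2] * (op[, 1] %in% c(OP_M, OP_X, OP_D))))
  readC <- cumsum(c(0L, op[, 2] * (op[, 1] != OP_D)))
  rows <- list()
  for (j in seq_len(nrow(op))) {
    l <- op[j, 2]
    if (op[j, 1] == OP_D && l >= minLen && l <= maxLen) {
      rows[[length(rows) + 1L]] <- data.frame(
        ref_id = rid, position = al$ref_start + refC[j],
        type = "DEL", length = l, alt = "", stringsAsFactors = FALSE)
    } else if (op[j, 1] == OP_I && l >= minLen && l <= maxLen) {
      rows[[length(rows) + 1L]] <- data.frame(
        ref_id = rid, position = al$ref_start - 1L + refC[j],
        type = "INS", length = l,
        alt = substr(consensus, readC[j] + 1L, readC[j] + l),
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows)) do.call(rbind, rows) else
    data.frame(ref_id = character(0), position = integer(0),
               type = character(0), length = integer(0), alt = character(0),
               stringsAsFactors = FALSE)
}
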