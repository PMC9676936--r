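# Structural-variant calling from SV-tolerant alignments: per-read indel
# operations >= sv_min_len are clustered by position across reads, emitted
# when supported by at least sv_min_support reads, classified as tandem
# duplications when the inserted sequence matches a flanking reference
# window, and merged across samples.

.emptySv <- function() {
  data.frame(ref_id = character(0), position = integer(0), type = character(0),
             length = integer(0), support = integer(0),
             sample_id = character(0), alt = character(0),
             stringsAsFactors = FALSE)
}

# per-read large indel events from an alignment set
.svEvents <- function(aln, minLen) {
  s <- alignmentSummary(aln)
  idx <- which(s$assignment == "unique")
  ops <- alignmentOps(aln)
  rows <- list()
  for (i in idx) {
    op <- ops[[i]]
    big <- which((op[, 1] == OP_I | op[, 1] == OP_D) & op[, 2] >= minLen)
    if (!length(big)) next
    refC <- cumsum(c(0L, op[, 2] * (op[, 1] %in% c(OP_M, OP_X, OP_D))))
    readC <- cumsum(c(0L, op[, 2] * (op[, 1] != OP_D)))
    for (j in big) {
      ins <- op[j, 1] == OP_I
      rows[[length(rows) + 1L]] <- data.frame(
        read_id = s$read_id[i], sample_id = s$sample_id[i],
        ref_id = s$ref_id[i],
        type = if (ins) "INS" else "DEL",
        position = if (ins) s$ref_start[i] - 1L + refC[j]
                   else s$ref_start[i] + refC[j],
        length = op[j, 2],
        alt = if (ins) substr(aln@seqs[i], readC[j] + 1L, readC[j] + op[j, 2])
              else "",
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows)) do.call(rbind, rows) else NULL
}

#' Call structural variants for one sample
#'
#' Insertion/deletion alignment operations of at least \code{sv_min_len}
#' bases from uniquely assigned reads are clustered across reads by
#' position (single linkage within \code{sv_cluster_window}); a call is
#' emitted when supported by at least \code{sv_min_support} reads, with the
#' median of member positions and lengths (robust to nanopore indel noise).
#'
#' @param aln an \linkS4class{AlignmentSet} for one sample
#' @param params a \linkS4class{PipelineParams}
#' @param sample_id sample label attached to the calls
#' @return data.frame of SV calls: ref_id, position, type (INS/DEL),
#'   length, support, sample_id, alt (inserted sequence)
#' @export
callSVs <- function(aln, params = pipelineParams(), sample_id = NA_character_) {
  ev <- .svEvents(aln, param(params, "sv_min_len"))
  if (is.null(ev)) return(.emptySv())
  win <- param(params, "sv_cluster_window")
  minSupp <- param(params, "sv_min_support")
  out <- list()
  for (key in unique(paste(ev$ref_id, ev$type))) {
    sub <- ev[paste(ev$ref_id, ev$type) == key, , drop = FALSE]
    sub <- sub[order(sub$position), , drop = FALSE]
    cl <- cumsum(c(1L, as.integer(diff(sub$position) > win)))
    for (g in unique(cl)) {
      m <- sub[cl == g, , drop = FALSE]
      supp <- length(unique(m$read_id))
      if (supp < minSupp) next
      len <- as.integer(round(median(m$length)))
      rep_i <- which.min(abs(m$length - len))
      out[[length(out) + 1L]] <- data.frame(
        ref_id = m$ref_id[1], position = as.integer(round(median(m$position))),
        type = m$type[1], length = len, support = supp,
        sample_id = sample_id, alt = m$alt[rep_i], stringsAsFactors = FALSE)
    }
  }
  if (length(out)) {
    res <- do.call(rbind, out)
    res[order(res$ref_id, res$position), , drop = FALSE]
  } else .emptySv()
}

.opsIdentity <- function(a, b, params) {
  if (as.double(nchar(a) + 1) * (nchar(b) + 1) <= 6.4e7) {
    r <- cpp_nw_ops(a, b, param(params, "aln_match"),
                    param(params, "aln_mismatch"),
                    param(params, "aln_gap_open"), param(params, "aln_gap_ext"))
    m <- sum(r$len[r$op == OP_M])
    m / sum(r$len)
  } else globalIdentity(a, b, params)
}

#' Classify insertion calls as tandem duplications
#'
#' An INS call whose inserted sequence aligns to the reference window
#' immediately flanking the insertion point (either side) with identity at
#' least \code{minIdent} is reclassified DUP. Calls without an inserted
#' sequence are left as INS and flagged.
#'
#' @param calls SV call data.frame from \code{\link{callSVs}}
#' @param ref the \linkS4class{HomoeologReference} the calls are on
#' @param minIdent duplication identity threshold (default 0.9)
#' @param params a \linkS4class{PipelineParams}
#' @return the calls with updated \code{type} and added \code{dup_identity}
#'   and \code{flag} columns
#' @export
classifyInsertion <- function(calls, ref, minIdent = 0.9,
                              params = pipelineParams()) {
  if (!nrow(calls)) {
    calls$dup_identity <- numeric(0); calls$flag <- character(0)
    return(calls)
  }
  refStr <- refSeq(ref)
  L <- nchar(refStr)
  calls$dup_identity <- NA_real_
  calls$flag <- ""
  for (i in which(calls$type == "INS")) {
    alt <- calls$alt[i]
    len <- calls$length[i]
    if (is.na(alt) || !nzchar(alt)) { calls$flag[i] <- "no_sequence"; next }
    p <- calls$position[i]
    idents <- c(
      if (p - len >= 0L) .opsIdentity(alt, substr(refStr, p - len + 1L, p),
                                      params) else NA_real_,
      if (p + len <= L) .opsIdentity(alt, substr(refStr, p + 1L, p + len),
                                     params) else NA_real_)
    best <- suppressWarnings(max(idents, na.rm = TRUE))
    if (is.finite(best)) {
      calls$dup_identity[i] <- best
      if (best >= minIdent) calls$type[i] <- "DUP"
    }
  }
  calls
}

#' Merge SV calls across samples into a population table
#'
#' Calls of the same type on the same reference whose positions lie within
#' \code{sv_merge_window} of each other (single linkage) collapse into one
#' record listing the carrier samples; different types never merge.
#'
#' @param calls combined per-sample SV call data.frame
#' @param params a \linkS4class{PipelineParams}
#' @return data.frame: ref_id, position, type, length (medians), carriers
#'   (comma-separated), n_carriers, support (total)
#' @export
mergeSVs <- function(calls, params = pipelineParams()) {
  if (!nrow(calls))
    return(data.frame(ref_id = character(0), position = integer(0),
                      type = character(0), length = integer(0),
                      carriers = character(0), n_carriers = integer(0),
                      support = integer(0), stringsAsFactors = FALSE))
  win <- param(params, "sv_merge_window")
  out <- list()
  for (key in unique(paste(calls$ref_id, calls$type))) {
    sub <- calls[paste(calls$ref_id, calls$type) == key, , drop = FALSE]
    sub <- sub[order(sub$position), , drop = FALSE]
    cl <- cumsum(c(1L, as.integer(diff(sub$position) > win)))
    for (g in unique(cl)) {
      m <- sub[cl == g, , drop = FALSE]
      carriers <- sort(unique(m$sample_id))
      out[[length(out) + 1L]] <- data.frame(
        ref_id = m$ref_id[1], position = as.integer(round(median(m$position))),
        type = m$type[1], length = as.integer(round(median(m$length))),
        carriers = paste(carriers, collapse = ","),
        n_carriers = length(carriers), support = sum(m$support),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  res[order(res$ref_id, res$position), , drop = FALSE]
}
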