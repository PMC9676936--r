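# Sequence-type assignment of consensus sequences against a labelled
# reference panel, and exact-match grouping of cultivars by their variant
# vectors.

#' Assign a consensus sequence to a reference panel type
#'
#' The best hit by global-alignment identity wins; ties break
#' alphabetically by label. A consensus whose best-hit identity falls
#' below \code{seqtype_identity} (default 0.99) is discarded.
#'
#' @param consensus consensus sequence (character)
#' @param panel named character vector (or list of
#'   \linkS4class{HomoeologReference}) of labelled reference sequences
#' @param params a \linkS4class{PipelineParams}
#' @return list: label, identity, status ("assigned" or "discarded"),
#'   identities (per panel entry)
#' @export
sequenceType <- function(consensus, panel, params = pipelineParams()) {
  if (!nzchar(consensus)) stop("empty consensus")
  if (length(panel) == 0) stop("empty reference panel")
  seqs <- if (is.list(panel))
    vapply(panel, function(p)
      if (is(p, "HomoeologReference")) refSeq(p) else p, "") else panel
  ids <- vapply(seqs, function(s) globalIdentity(consensus, s, params), 0)
  o <- order(-ids, names(seqs))
  best <- o[1]
  status <- if (ids[best] < param(params, "seqtype_identity")) "discarded"
            else "assigned"
  list(label = names(seqs)[best], identity = unname(ids[best]),
       status = status, identities = ids)
}

# normalise a genotype entry: het pairs are unordered ("T/C" == "C/T")
.normCall <- function(x) {
  if (is.na(x)) return(NA_character_)
  if (grepl("/", x, fixed = TRUE)) {
    p <- sort(strsplit(x, "/", fixed = TRUE)[[1]])
    paste(p, collapse = "/")
  } else x
}

#' Group samples by exact-match variant vectors
#'
#' Two samples share a group iff their (filter-passing) variant vectors
#' are identical; heterozygous calls are unordered allele pairs; missing
#' values match nothing, so a sample with missing data forms its own
#' group. Group labels are ordered by descending size, then first
#' occurrence.
#'
#' @param mat character matrix samples x sites ("C", "C/T", NA, "-")
#' @param prefix group-label prefix (default "GT")
#' @return list: assignment data.frame (sample, group, vector), n_groups
#' @export
genotypeGroups <- function(mat, prefix = "GT") {
  if (is.null(dim(mat)) || nrow(mat) == 0) stop("empty variant matrix")
  norm <- apply(mat, c(1, 2), .normCall)
  if (is.null(dim(norm))) norm <- matrix(norm, nrow = nrow(mat),
                                         dimnames = dimnames(mat))
  hasNA <- apply(is.na(norm), 1, any)
  key <- apply(norm, 1, function(r) paste(r, collapse = "|"))
  key[hasNA] <- paste0(".missing.", seq_len(nrow(norm))[hasNA])
  firstSeen <- !duplicated(key)
  sizes <- table(key)[unique(key)]
  ord <- order(-as.integer(sizes), match(names(sizes), key))
  lab <- setNames(paste0(prefix, seq_along(sizes)), names(sizes)[ord])
  grp <- lab[key]
  samples <- rownames(mat)
  if (is.null(samples)) samples <- paste0("sample", seq_len(nrow(mat)))
  list(assignment = data.frame(sample = samples, group = unname(grp),
                               vector = key, stringsAsFactors = FALSE),
       n_groups = length(sizes))
}

#' Group samples by presence/absence of defining variants
#'
#' Grouping over the presence/absence vector of a small defining-variant
#' set (e.g. a 163 bp insertion, a 17 bp deletion and one intron SNP for
#' the D homoeolog); the all-absent row is the intact reference group.
#'
#' @param presence logical matrix samples x variants
#' @param prefix group-label prefix (default "Hap")
#' @return list as in \code{\link{genotypeGroups}}; the intact group is
#'   labelled first when present
#' @export
presenceGroups <- function(presence, prefix = "Hap") {
  if (is.null(dim(presence)) || nrow(presence) == 0)
    stop("empty presence matrix")
  mat <- ifelse(presence, "1", "0")
  rownames(mat) <- rownames(presence)
  genotypeGroups(mat, prefix = prefix)
}
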