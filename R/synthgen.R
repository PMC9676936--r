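# Synthetic homoeolog references, allele edits, read panels and phenotypes.
# All positions are 1-based counted from the amplicon start (3' end of the
# forward primer); internal arithmetic is 0-based half-open only inside the
# compiled alignment core.

# Fixed feature geometry for the default amplicon: a 700 bp promoter stub,
# a long first intron (the bulk of the amplified target) and seven further
# exon/intron pairs. All feature sizes are fixed except intron 1, which
# absorbs the remaining gene length.
.featFixed <- c(exon1 = 1050L, exon2 = 80L, intron2 = 210L, exon3 = 70L,
                intron3 = 30L, exon4 = 70L, intron4 = 220L, exon5 = 60L,
                intron5 = 100L, exon6 = 60L, intron6 = 80L, exon7 = 100L,
                intron7 = 200L)

#' Feature map for a synthetic homoeolog amplicon
#'
#' Builds the named promoter/exon/intron intervals tiling an amplicon of
#' \code{promoterLen + geneLen} bases. Intron 1 absorbs all gene length not
#' taken by the fixed-size features, mirroring the dominance of the first
#' intron in the real amplicon (about 70 percent of the target).
#'
#' @param promoterLen promoter length (default 700)
#' @param geneLen gene-body length (>= 10000)
#' @return named \link[IRanges]{IRanges}
#' @export
buildFeatureMap <- function(promoterLen = 700L, geneLen = 13000L) {
  promoterLen <- as.integer(promoterLen); geneLen <- as.integer(geneLen)
  fixedSum <- sum(.featFixed)
  exon8 <- 1720L
  intron1 <- geneLen - fixedSum - exon8
  if (intron1 < 1000L) stop("gene length too short for the feature geometry")
  lens <- c(promoter = promoterLen, exon1 = .featFixed[["exon1"]],
            intron1 = intron1,
            .featFixed[setdiff(names(.featFixed), "exon1")], exon8 = exon8)
  ends <- cumsum(lens)
  starts <- ends - lens + 1L
  IRanges::IRanges(start = as.integer(starts), end = as.integer(ends),
                   names = names(lens))
}

# G-rich motifs planted in the shared ancestor so each reference carries
# QGRS-eligible targets in the promoter and first intron.
.plantedG4 <- "GGGTTAGGGTTAGGGTTAGGG"

.g4Sites <- function(features) {
  pr <- features["promoter"]
  i1 <- features["intron1"]
  c(promoter = IRanges::start(pr) + 439L,
    intron1a = IRanges::start(i1) + 4039L,
    intron1b = IRanges::end(i1) - 1200L)
}

#' Allele edit descriptors
#'
#' An allele edit is a SNP, insertion (INS), deletion (DEL) or tandem
#' duplication (DUP) at a 1-based position. INS inserts \code{alt} after
#' \code{position}; DEL removes \code{length} bases starting at
#' \code{position}; DUP inserts a tandem copy of the \code{length} bases
#' ending at \code{position} immediately after it (\code{alt}, when
#' non-empty, replaces the copied bases, allowing near-identical
#' duplications); SNP substitutes the single base at \code{position} with
#' \code{alt}.
#'
#' @param kind "SNP", "INS", "DEL" or "DUP"
#' @param position 1-based position
#' @param length edit length in bases (1 for SNP)
#' @param alt inserted/substituted bases ("" for DEL and exact DUP)
#' @return a data.frame with one row per edit
#' @export
alleleEdit <- function(kind = character(0), position = integer(0),
                       length = rep(1L, base::length(kind)),
                       alt = rep("", base::length(kind))) {
  stopifnot(all(kind %in% c("SNP", "INS", "DEL", "DUP")))
  data.frame(kind = as.character(kind), position = as.integer(position),
             length = as.integer(length), alt = as.character(alt),
             stringsAsFactors = FALSE)
}

#' @rdname alleleEdit
#' @param ... allele-edit data frames to combine (sorted by position)
#' @export
combineEdits <- function(...) {
  e <- do.call(rbind, list(...))
  e[order(e$position), , drop = FALSE]
}

#' Apply allele edits to a reference sequence
#'
#' Edits must be sorted by position and non-overlapping; they are applied
#' right-to-left so that earlier positions stay valid. The output length is
#' the input length plus the sum of signed edit lengths.
#'
#' @param ref a \linkS4class{HomoeologReference} or character sequence
#' @param edits allele-edit data frame (see \code{\link{alleleEdit}})
#' @return edited sequence (character)
#' @export
applyAllele <- function(ref, edits) {
  seq <- if (is(ref, "HomoeologReference")) refSeq(ref) else ref
  if (is.null(edits) || nrow(edits) == 0) return(seq)
  if (is.unsorted(edits$position)) stop("edits must be sorted by position")
  n <- nchar(seq)
  foot <- cbind(edits$position,
                ifelse(edits$kind == "DEL", edits$position + edits$length - 1L,
                       edits$position))
  if (any(foot[, 1] < 1L) || any(foot[, 2] > n))
    stop("edit position out of range")
  if (nrow(edits) > 1 && any(foot[-1, 1] <= foot[-nrow(edits), 2]))
    stop("overlapping edits")
  ch <- seqChars(seq)
  for (i in rev(seq_len(nrow(edits)))) {
    k <- edits$kind[i]; p <- edits$position[i]; l <- edits$length[i]
    a <- edits$alt[i]
    if (k == "SNP") {
      if (nchar(a) != 1L) stop("SNP alt must be a single base")
      if (a == ch[p]) stop("SNP alt equals the reference base at ", p)
      ch[p] <- a
    } else if (k == "DEL") {
      ch <- ch[-(p:(p + l - 1L))]
    } else if (k == "INS") {
      if (nchar(a) < 1L) stop("INS needs alt bases")
      ch <- append(ch, seqChars(a), after = p)
    } else {  # DUP: tandem copy of the length bases ending at position
      if (p - l < 0L) stop("DUP window out of range")
      cp <- if (nzchar(a)) seqChars(a) else ch[(p - l + 1L):p]
      if (length(cp) != l) stop("DUP alt must have the stated length")
      ch <- append(ch, cp, after = p)
    }
  }
  paste(ch, collapse = "")
}

# force non-homopolymeric, motif-free context around planted sites: bases at
# pos-4..pos+4 are rewritten so adjacent bases always differ (deterministic).
# `avoid` optionally lists, per site (keyed by position), alleles kept out of
# the window so alternate-allele read bases cannot pair with a neighbouring
# reference base and shift the variant onto a gap (reference-bias guard).
.cleanContext <- function(ch, sites, avoid = NULL) {
  n <- length(ch)
  fixed <- logical(n)
  fixed[sites] <- TRUE  # planted centres are never rewritten as neighbours
  cyc <- c("A", "C", "G", "T")
  for (p in sort(sites)) {
    av <- if (!is.null(avoid)) avoid[[as.character(p)]] else NULL
    for (q in max(1L, p - 4L):min(n, p + 4L)) {
      if (q == p || fixed[q]) next
      left <- if (q > 1L) ch[q - 1L] else ""
      right <- if (q < n) ch[q + 1L] else ""
      cand <- setdiff(cyc, c(left, right, "G", av))
      if (!length(cand)) cand <- setdiff(cyc, c(left, right, "G"))
      ch[q] <- cand[1L]
      fixed[q] <- TRUE
    }
    # keep the centre base but break any run it would extend
    fixed[p] <- TRUE
  }
  ch
}

#' Generate three homoeolog references from a common ancestor
#'
#' A random ancestor amplicon is generated, G-rich quadruplex-eligible
#' motifs are planted in the promoter and first intron, and three
#' references diverge from the ancestor by independent mutation (90 percent
#' substitutions, 10 percent 1-5 bp indels) calibrated so the pairwise
#' global-alignment identity matches \code{targetIdentity} within 0.02.
#'
#' @param seed integer seed; generation is fully deterministic
#' @param targetIdentity pairwise identity target in (0.5, 1]
#' @param geneLen gene-body length (>= 10000)
#' @param promoterLen promoter length
#' @param ids reference labels
#' @param cleanSites positions forced to a non-homopolymeric context in all
#'   three references (kept mutation-free), for downstream variant planting
#' @return named list of \linkS4class{HomoeologReference}; the pairwise
#'   identity matrix (as measured by the package aligner) is attached as
#'   attribute \code{"identity"}
#' @export
generateReferences <- function(seed, targetIdentity = 0.92, geneLen = 13000L,
                               promoterLen = 700L, ids = c("A", "B", "D"),
                               cleanSites = integer(0)) {
  if (targetIdentity <= 0.5 || targetIdentity > 1)
    stop("targetIdentity must be in (0.5, 1]")
  if (geneLen < 10000L) stop("geneLen must be >= 10000")
  set.seed(seed)
  total <- promoterLen + geneLen
  feats <- buildFeatureMap(promoterLen, geneLen)
  anc <- seqChars(randSeq(total))
  g4 <- .g4Sites(feats)
  motif <- seqChars(.plantedG4)
  for (p in g4) anc[p:(p + length(motif) - 1L)] <- motif
  if (length(cleanSites)) anc <- .cleanContext(anc, cleanSites)
  # positions never mutated: planted motifs (+2 bp margin) and clean sites
  protect <- logical(total)
  for (p in g4) protect[max(1L, p - 2L):min(total, p + length(motif) + 1L)] <- TRUE
  for (p in cleanSites) protect[max(1L, p - 5L):min(total, p + 5L)] <- TRUE
  ancSeq <- paste(anc, collapse = "")

  if (targetIdentity == 1) {
    refs <- lapply(ids, function(id)
      homoeologReference(id, ancSeq, promoterLen, feats))
    names(refs) <- ids
    im <- matrix(1, 3, 3, dimnames = list(ids, ids))
    attr(refs, "identity") <- im
    return(refs)
  }

  branch <- function(rate) {
    # one mutated branch: substitutions 90%, 1-5 bp indels 10% of events
    nEv <- max(1L, round(rate * total))
    pos <- sort(sample(which(!protect), min(nEv, sum(!protect))))
    # enforce >= 7 bp spacing so edits never overlap
    keep <- c(TRUE, diff(pos) >= 7L)
    pos <- pos[keep]
    kind <- ifelse(runif(length(pos)) < 0.9, "SNP",
                   ifelse(runif(length(pos)) < 0.5, "INS", "DEL"))
    len <- ifelse(kind == "SNP", 1L, sample(1:5, length(pos), replace = TRUE))
    alt <- character(length(pos))
    for (i in seq_along(pos)) {
      if (kind[i] == "SNP") alt[i] <- sample(setdiff(BASES, anc[pos[i]]), 1)
      else if (kind[i] == "INS") alt[i] <- randSeq(len[i])
    }
    ok <- !(kind == "DEL" & pos + len - 1L > total)
    e <- alleleEdit(kind[ok], pos[ok], len[ok], alt[ok])
    applyAllele(ancSeq, e)
  }

  # per-branch event rate: each event costs about 1.2 alignment columns and
  # two branches separate a pair
  rate <- (1 - targetIdentity) / 2.4
  for (iter in 1:4) {
    seqs <- lapply(seq_along(ids), function(i) branch(rate))
    idm <- matrix(1, length(ids), length(ids), dimnames = list(ids, ids))
    for (i in 1:(length(ids) - 1)) for (j in (i + 1):length(ids))
      idm[i, j] <- idm[j, i] <- globalIdentity(seqs[[i]], seqs[[j]])
    mean_id <- mean(idm[upper.tri(idm)])
    if (abs(mean_id - targetIdentity) <= 0.015) break
    rate <- rate * (1 - targetIdentity) / max(1e-6, (1 - mean_id))
  }
  if (abs(mean_id - targetIdentity) > 0.02)
    stop("could not attain the requested identity")
  refs <- lapply(seq_along(ids), function(i)
    homoeologReference(ids[i], seqs[[i]], promoterLen,
                       buildFeatureMap(promoterLen,
                                       nchar(seqs[[i]]) - promoterLen)))
  names(refs) <- ids
  attr(refs, "identity") <- idm
  refs
}

#' Deterministic ONT-like barcode set
#'
#' Generates \code{n} 24-base barcodes with pairwise edit distance >= 8
#' (greedy rejection from a fixed RNG stream), analogous to a 96-barcode
#' PCR barcoding expansion.
#'
#' @param n number of barcodes (<= 96)
#' @param width barcode length
#' @return character vector of barcodes
#' @export
ontLikeBarcodes <- function(n = 96L, width = 24L) {
  if (n > 96L) stop("at most 96 barcodes supported")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(104729L)  # fixed: the barcode set is a constant of the package
  out <- character(0)
  while (length(out) < n) {
    cand <- randSeq(width)
    ok <- TRUE
    for (b in out) {
      d <- nrow(cpp_scan_barcode(b, cand, 7L))
      if (d > 0) { ok <- FALSE; break }
    }
    if (ok) out <- c(out, cand)
  }
  out
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

# per-template homopolymer indel multiplier vector
.hpMultVec <- function(ch, hpRun, hpMult) {
  r <- rle(ch)
  mult <- rep(ifelse(r$lengths >= hpRun, hpMult, 1), r$lengths)
  mult
}

# introduce per-base errors into a template substring; returns list(seq, parts)
# where parts gives post-error lengths of the supplied parts (for truth
# bookkeeping of barcode/insert boundaries)
.mutateParts <- function(parts, em, hpVecs) {
  outParts <- character(length(parts))
  for (k in seq_along(parts)) {
    ch <- seqChars(parts[[k]])
    n <- length(ch)
    if (n == 0) { outParts[k] <- ""; next }
    mult <- hpVecs[[k]]
    if (is.null(mult)) mult <- rep(1, n)
    subHit <- runif(n) < em@sub
    if (any(subHit)) {
      idx <- which(subHit)
      repl <- BASES[(match(ch[idx], BASES) - 1L +
                     sample(1:3, length(idx), replace = TRUE)) %% 4L + 1L]
      ch[idx] <- repl
    }
    keep <- runif(n) >= pmin(em@del * mult, 0.95)
    insHit <- runif(n) < pmin(em@ins * mult, 0.95)
    nIns <- sum(insHit)
    if (nIns > 0 || !all(keep)) {
      key <- c(seq_len(n)[keep], which(insHit) + 0.5)
      val <- c(ch[keep],
               if (nIns) sample(BASES, nIns, replace = TRUE) else character(0))
      ch <- val[order(key)]
    }
    outParts[k] <- paste(ch, collapse = "")
  }
  outParts
}

.emitQuals <- function(len, em) {
  pTot <- em@sub + em@ins + em@del
  baseQ <- if (pTot <= 0) 40 else min(40, -10 * log10(pTot))
  shift <- rnorm(1, 0, em@qualReadSd)
  q <- round(baseQ + shift + rnorm(len, 0, em@qualSd))
  pmin(pmax(q, 2L), 41L)
}

#' Simulate a barcoded amplicon read panel
#'
#' For each cultivar genotype, template copies are built by applying the
#' copy's allele edits to its homoeolog reference; reads are sampled from
#' the copies proportionally to their amplification weights, barcoded at
#' both ends (forward barcode at the head, its reverse complement at the
#' tail), subjected to per-base errors from the error model, optionally
#' fused into chimeric molecules, and strand-flipped at random. The truth
#' table records cultivar, homoeolog, copy, haplotype, chimera and
#' barcode-loss flags per read.
#'
#' @param genotypes list of \linkS4class{CultivarGenotype}
#' @param refs named list of \linkS4class{HomoeologReference}
#' @param meanCoverage expected per-homoeolog spanning depth
#' @param em an \linkS4class{ErrorModel}
#' @param barcodes character vector, at least one barcode per genotype
#' @param seed integer seed (full determinism: equal seeds give identical
#'   panels)
#' @param fullLengthFrac fraction of reads spanning the whole template
#' @param minReadLen minimum partial-read length
#' @return a \linkS4class{SimPanel}
#' @export
simulatePanel <- function(genotypes, refs, meanCoverage, em = errorModel(),
                          barcodes = ontLikeBarcodes(length(genotypes)),
                          seed = 1L, fullLengthFrac = 0.85,
                          minReadLen = 500L) {
  if (length(genotypes) == 0) stop("empty genotype list")
  if (meanCoverage <= 0) stop("meanCoverage must be positive")
  if (length(barcodes) < length(genotypes))
    stop("need at least one barcode per genotype")
  set.seed(seed)
  barcodes <- barcodes[seq_along(genotypes)]
  names(barcodes) <- vapply(genotypes, function(g) g@cultivar, "")

  seqs <- character(0); quals <- list()
  truth <- list()
  molDesc <- list()  # for chimera partners: raw molecules w/o strand flips
  ri <- 0L
  for (gi in seq_along(genotypes)) {
    g <- genotypes[[gi]]
    bc <- barcodes[[gi]]
    homs <- unique(vapply(g@copies, function(cp) cp$homoeolog, ""))
    # homoeolog-level amplification: read totals scale with the summed
    # copy weights of each homoeolog relative to the genotype mean, so a
    # strongly amplifying short allele (deletion carrier) starves the
    # other homoeologs, as seen with preferential PCR of short amplicons
    homW <- vapply(homs, function(h)
      sum(vapply(Filter(function(cp) cp$homoeolog == h, g@copies),
                 function(cp) cp$weight, 0)), 0)
    homFac <- if (mean(homW) > 0) homW / mean(homW) else rep(1, length(homs))
    names(homFac) <- homs
    for (h in homs) {
      cps <- Filter(function(cp) cp$homoeolog == h, g@copies)
      tmpl <- lapply(cps, function(cp) applyAllele(refs[[h]], cp$edits))
      hpv <- lapply(tmpl, function(s) .hpMultVec(seqChars(s), em@hpRun, em@hpMult))
      w <- vapply(cps, function(cp) cp$weight, 0)
      if (sum(w) <= 0) next
      L <- mean(nchar(unlist(tmpl)))
      cbar <- fullLengthFrac + (1 - fullLengthFrac) *
        ((minReadLen + L) / 2) / L
      nTot <- max(1L, round(meanCoverage * homFac[[h]] / cbar))
      cnt <- as.vector(rmultinom(1, nTot, w / sum(w)))
      for (ci in seq_along(cps)) {
        if (cnt[ci] == 0) next
        tl <- nchar(tmpl[[ci]])
        for (r in seq_len(cnt[ci])) {
          ri <- ri + 1L
          full <- runif(1) < fullLengthFrac
          if (full || tl <= minReadLen) { s <- 1L; e <- tl }
          else {
            len <- sample(minReadLen:tl, 1)
            s <- sample(seq_len(tl - len + 1L), 1); e <- s + len - 1L
          }
          insert <- substr(tmpl[[ci]], s, e)
          lost <- runif(1) < em@barcodeLossProb
          parts <- if (lost) list(insert) else list(bc, insert, revComp(bc))
          mut <- .mutateParts(parts, em,
                              if (lost) list(hpv[[ci]][s:e])
                              else list(NULL, hpv[[ci]][s:e], NULL))
          mol <- paste(mut, collapse = "")
          molDesc[[ri]] <- mol
          truth[[ri]] <- data.frame(
            read_id = sprintf("read%06d", ri), cultivar = g@cultivar,
            homoeolog = h, copy = ci, haplotype = cps[[ci]]$haplotype,
            template_start = s, template_end = e,
            barcode_lost = lost, chimera = FALSE, strand = "+",
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  n <- ri
  if (n == 0) stop("no reads simulated (zero coverage?)")
  truth <- do.call(rbind, truth)
  mol <- unlist(molDesc)

  # chimeric molecules: fuse with an independently chosen partner molecule
  chim <- runif(n) < em@chimeraProb
  if (any(chim)) {
    partner <- sample(n, sum(chim), replace = TRUE)
    mol[chim] <- paste0(mol[chim], mol[partner])
    truth$chimera <- chim
    truth$partner_cultivar <- NA_character_
    truth$partner_cultivar[chim] <- truth$cultivar[partner]
  } else {
    truth$partner_cultivar <- NA_character_
  }

  flip <- runif(n) < 0.5
  mol[flip] <- vapply(mol[flip], revComp, "", USE.NAMES = FALSE)
  truth$strand[flip] <- "-"

  qv <- lapply(nchar(mol), .emitQuals, em = em)
  reads <- Biostrings::DNAStringSet(mol)
  names(reads) <- truth$read_id
  qstr <- vapply(qv, function(q) rawToChar(as.raw(q + 33L)), "")
  quals <- Biostrings::BStringSet(qstr)
  names(quals) <- truth$read_id
  rownames(truth) <- NULL
  new("SimPanel", reads = reads, quals = quals, truth = truth,
      barcodes = barcodes)
}

#' Default 20-trait phenotype model
#'
#' Trait names, baselines and dispersions follow a central-European winter
#' wheat trial: grain yield (dt/ha), biomass (t/ha), thousand-kernel weight
#' (g), sedimentation value, falling number (s), kernels per spike, kernels
#' per m2, spikes per m2, harvest index, plant height (cm), heading date
#' (d), nitrogen-use efficiency, stripe rust and powdery mildew scores,
#' crude protein (pct), protein yield (kg/ha), radiation-use efficiency,
#' radiation-interception efficiency, green canopy duration (degree-days)
#' and nodal root-angle index.
#'
#' @param effects optional group-effect matrix (groups x traits)
#' @return a \linkS4class{PhenoModel}
#' @export
defaultPhenoModel <- function(effects = NULL) {
  traits <- c("grain_yield", "biomass", "tkw", "sedimentation",
              "falling_number", "kernels_per_spike", "kernels_per_m2",
              "spikes_per_m2", "harvest_index", "plant_height",
              "heading_date", "nue", "stripe_rust", "powdery_mildew",
              "crude_protein", "protein_yield", "rue", "rie", "gcd", "nri")
  baseline <- c(95, 18, 46, 38, 300, 45, 22000, 520, 0.48, 92,
                155, 1.0, 85, 80, 12.5, 1150, 2.9, 0.62, 820, 0.35)
  sdv <- c(6, 1.4, 3, 6, 40, 5, 2200, 55, 0.03, 6,
           3, 0.08, 12, 14, 0.8, 90, 0.2, 0.04, 60, 0.12)
  if (is.null(effects)) effects <- matrix(0, 0, length(traits),
                                          dimnames = list(NULL, traits))
  new("PhenoModel", traits = traits, baseline = baseline, sd = sdv,
      effects = effects)
}

#' Simulate group-structured phenotypes
#'
#' Each trait value is baseline + additive group effect + Gaussian noise.
#'
#' @param groups either a named character vector (sample -> group) or a
#'   character vector of group labels used with \code{nPerGroup}
#' @param model a \linkS4class{PhenoModel}
#' @param nPerGroup samples per group when \code{groups} are bare labels
#' @param seed integer seed
#' @return data.frame with columns \code{sample}, \code{group} and one
#'   column per trait
#' @export
simulatePhenotypes <- function(groups, model = defaultPhenoModel(),
                               nPerGroup = NULL, seed = 1L) {
  set.seed(seed)
  if (is.null(names(groups)) && !is.null(nPerGroup)) {
    glab <- rep(groups, each = nPerGroup)
    snam <- paste0(glab, "_", sequence(rep(nPerGroup, length(groups))))
  } else if (!is.null(names(groups))) {
    glab <- unname(groups); snam <- names(groups)
  } else stop("groups must be named or nPerGroup given")
  if (length(glab) == 0) stop("groups are empty")
  nt <- length(model@traits)
  out <- matrix(NA_real_, length(glab), nt,
                dimnames = list(snam, model@traits))
  for (j in seq_len(nt)) {
    eff <- rep(0, length(glab))
    if (nrow(model@effects) > 0) {
      hit <- glab %in% rownames(model@effects)
      eff[hit] <- model@effects[glab[hit], j]
    }
    out[, j] <- model@baseline[j] + eff + rnorm(length(glab), 0, model@sd[j])
  }
  data.frame(sample = snam, group = glab, out, row.names = NULL,
             stringsAsFactors = FALSE)
}
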