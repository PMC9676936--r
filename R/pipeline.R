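# End-to-end pipeline: simulate -> demux -> align -> consensus -> call SVs
# and small variants -> phase/copy-number -> group -> G4 scan -> associate.
# Every stage writes its outputs in standard formats into the run
# directory, and a provenance manifest records seeds, parameters and the
# read-count funnel (raw >= classified >= filtered >= assigned).

#' Run the full analysis pipeline on a synthetic panel
#'
#' @param config list with optional entries: \code{groups} (genotype
#'   groups to simulate, default GT1-GT6), \code{coverage} (default 60),
#'   \code{errorModel} (list of \code{\link{errorModel}} arguments),
#'   \code{targetIdentity} (default 0.92), \code{traits} (number of
#'   phenotype samples per group for association, default 15)
#' @param outDir run directory (created)
#' @param seed integer seed; identical seeds give identical outputs
#' @param params a \linkS4class{PipelineParams}
#' @return (invisibly) list with all stage results and the manifest
#' @export
runPipeline <- function(config = list(), outDir, seed = 1L,
                        params = pipelineParams()) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  groups <- config$groups %||% c("GT1", "GT2", "GT3", "GT4", "GT5", "GT6")
  coverage <- config$coverage %||% 60
  emArgs <- config$errorModel %||% list()
  em <- do.call(errorModel, emArgs)
  targetIdentity <- config$targetIdentity %||% 0.92
  nPheno <- config$traits %||% 15L

  # stage 1: references + simulation
  refs <- vrnPanelReferences(seed, targetIdentity)
  writeRefsFasta(refs, file.path(outDir, "references.fasta"))
  genos <- vrnA1PanelGenotypes(groups)
  panel <- simulatePanel(genos, refs, coverage, em, seed = seed + 1L)
  writePanelFastq(panel, file.path(outDir, "reads.fastq"))
  writeTsv(panelTruth(panel), file.path(outDir, "truth.tsv"))

  # stage 2: demultiplex + filter
  dmx <- demuxPanel(panel, params = params)
  writeTsv(dmx, file.path(outDir, "demux.tsv"))
  keep <- dmx$status == "assigned"

  # stage 3: align assigned reads
  reads <- as.character(panelReads(panel))[keep]
  aln <- alignPanel(reads, refs, params, sample_ids = dmx$sample_id[keep])
  writeTsv(alignmentSummary(aln), file.path(outDir, "alignments.tsv"))
  cov <- coverageStats(aln, refs, param(params, "low_coverage"))
  writeTsv(data.frame(sample = rownames(cov$depth), cov$depth,
                      check.names = FALSE),
           file.path(outDir, "coverage.tsv"))

  # stage 4: per-sample consensus, SV and small-variant calls on VRN-A1
  samples <- sort(unique(alignmentSummary(aln)$sample_id))
  svAll <- list(); callsBySample <- list(); consensi <- list()
  cnCalls <- list()
  tbA <- vrnA1SiteTable()
  for (smp in samples) {
    pu <- buildPileup(aln, refs$A, sample = smp)
    if (pu@nReads == 0) next
    sv <- callSVs(subsetAlignments(aln, smp), params, sample_id = smp)
    sv <- classifyInsertion(sv, refs$A, params = params)
    svAll[[smp]] <- sv
    cons <- tryCatch(referenceGuidedConsensus(pu, refs$A,
                                              param(params, "consensus_min_reads")),
                     lowCoverageError = function(e) NULL)
    consensi[[smp]] <- cons
    calls <- callVariants(pu, refs$A, params)
    calls <- homopolymerFilter(calls, refs$A, params)
    callsBySample[[smp]] <- calls
    # copy number at the diagnostic exon-4 dosage site when heterozygous
    pc <- passCalls(calls)
    dosSite <- 11109L
    hetHere <- pc[pc$position == dosSite & pc$zygosity == "het", , drop = FALSE]
    hetSites <- pc$position[pc$zygosity == "het"]
    hetSites <- setdiff(hetSites, 381L)  # G/C-repeat-analog site excluded
    if (length(hetSites) >= 1) {
      alleles <- lapply(hetSites, function(p) {
        row <- pc[pc$position == p, ][1, ]
        unique(na.omit(c(row$ref, row$alt, row$alt2)))
      })
      hs <- phaseHaplotypes(subsetAlignments(aln, smp), hetSites,
                            alleles = alleles, params = params,
                            refIdUse = "A")
    } else {
      hs <- new("HaplotypeSet", sites = integer(0),
                haplotypes = data.frame(haplotype = "ref", support = pu@nReads),
                ambiguous = 0L, spanning = pu@nReads, status = "phased")
    }
    if (nrow(hetHere)) {
      alt <- if (hetHere$alt[1] == hetHere$ref[1]) hetHere$alt2[1] else hetHere$alt[1]
      dos <- dosageFromAlignments(subsetAlignments(aln, smp), refs$A,
                                  dosSite, hetHere$ref[1], alt, params)
      cn <- copyNumberCall(hs, dos, "het", dosSite)
    } else {
      cn <- copyNumberCall(hs, NULL, "hom", dosSite)
    }
    cnCalls[[smp]] <- data.frame(
      sample = smp, n_haplotypes = cn@nHaplotypes, cluster = cn@cluster,
      frequency = round(cn@frequency, 3), copy_number = cn@copyNumber,
      evidence = cn@evidence, stringsAsFactors = FALSE)
  }
  svTab <- do.call(rbind, svAll)
  if (is.null(svTab)) svTab <- .emptySv()
  merged <- mergeSVs(svTab, params)
  writeVcf(svTab, refs, file.path(outDir, "sv.vcf"), type = "sv")
  writeTsv(merged, file.path(outDir, "sv_merged.tsv"))
  writeVcf(do.call(rbind, callsBySample), refs,
           file.path(outDir, "snp.vcf"), type = "snp")
  cnTab <- do.call(rbind, cnCalls)
  if (!is.null(cnTab)) writeTsv(cnTab, file.path(outDir, "copynumber.tsv"))

  # stage 5: genotype grouping from the call matrix at the published sites
  mat <- .callMatrix(callsBySample, tbA)
  grp <- genotypeGroups(mat)
  writeTsv(grp$assignment, file.path(outDir, "groups.tsv"))

  # stage 6: G4 scan on the three references
  g4 <- lapply(refs, function(r) findG4(refSeq(r)))
  for (h in names(g4))
    writeG4Bed(g4[[h]], h, file.path(outDir, paste0("g4_", h, ".bed")))

  # stage 7: phenotype association (SV carriers vs intact)
  svGroups <- setNames(ifelse(samples %in% unique(svTab$sample_id),
                              "SV", "intact"), samples)
  effects <- matrix(0, 1, 20,
                    dimnames = list("SV", defaultPhenoModel()@traits))
  effects["SV", "grain_yield"] <- -9.5
  pm <- defaultPhenoModel(effects)
  assignment <- setNames(rep(unname(svGroups), each = nPheno),
                         paste0(rep(samples, each = nPheno), "_",
                                seq_len(nPheno)))
  pheno <- simulatePhenotypes(assignment, pm, seed = seed + 2L)
  writeTsv(pheno, file.path(outDir, "phenotypes.tsv"))
  assoc <- associationReport(pheno, "group", alpha = param(params, "alpha"))
  writeTsv(assoc, file.path(outDir, "association.tsv"))

  funnel <- c(raw = nrow(dmx),
              classified = sum(dmx$status != "unclassified"),
              filtered = sum(dmx$status %in% c("assigned")),
              assigned = sum(alignmentSummary(aln)$assignment == "unique"))
  manifest <- list(
    package = "homeoplex",
    version = as.character(utils::packageVersion("homeoplex")),
    seed = seed, parameters = params@values,
    config = list(groups = groups, coverage = coverage,
                  targetIdentity = targetIdentity),
    funnel = as.list(funnel),
    n_sv_calls = nrow(svTab), n_merged_sv = nrow(merged),
    n_variant_sites = length(unique(passCallsAll(callsBySample)$position)),
    n_groups = grp$n_groups)
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(refs = refs, panel = panel, demux = dmx, alignments = aln,
                 coverage = cov, sv = svTab, sv_merged = merged,
                 calls = callsBySample, copy_number = cnTab, groups = grp,
                 g4 = g4, association = assoc, manifest = manifest))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Subset an alignment set to one sample
#'
#' @param aln an \linkS4class{AlignmentSet}
#' @param sample sample id
#' @return an \linkS4class{AlignmentSet}
#' @export
subsetAlignments <- function(aln, sample) {
  keep <- which(alignmentSummary(aln)$sample_id %in% sample)
  new("AlignmentSet", summary = aln@summary[keep, , drop = FALSE],
      ops = aln@ops[keep], seqs = aln@seqs[keep])
}

# variant-call matrix (samples x published sites) for grouping
.callMatrix <- function(callsBySample, siteTable) {
  samples <- names(callsBySample)
  mat <- matrix(NA_character_, length(samples), nrow(siteTable),
                dimnames = list(samples, siteTable$site))
  for (si in seq_along(samples)) {
    pc <- passCalls(callsBySample[[si]])
    for (k in seq_len(nrow(siteTable))) {
      p <- siteTable$position[k]
      row <- pc[pc$position == p, , drop = FALSE]
      if (!nrow(row)) { mat[si, k] <- siteTable$ref[k]; next }
      r <- row[1, ]
      mat[si, k] <- if (!is.na(r$zygosity) && r$zygosity == "het") {
        a2 <- if (!is.na(r$alt2)) r$alt2 else r$ref
        paste(sort(c(r$alt, a2)), collapse = "/")
      } else r$alt
    }
  }
  mat
}

passCallsAll <- function(callsBySample) {
  out <- do.call(rbind, lapply(callsBySample, passCalls))
  if (is.null(out)) .emptyCalls() else out
}
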