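## Orchestration: the full annotation build (map -> coding filter ->
## length filter -> cluster -> segment -> assign -> prune), the expression
## analysis (normalize -> summarize -> GNI -> SI -> DE), and a one-call
## generator of a complete synthetic test workspace.

#' Build the custom lncRNA annotation
#'
#' Runs the whole annotation pipeline: probes are mapped to the genome by
#' exact unique matching, probes overlapping coding exons on the same
#' strand are excluded, lncRNAs of 200 nt or shorter are discarded,
#' surviving lncRNAs are clustered by same-strand exon overlap, clusters
#' are segmented into probe sets at exon boundaries, probes are assigned
#' by containment, and empty probe sets / clusters are pruned.
#'
#' @param genome genome (FASTA path, \code{DNAStringSet} or named
#'   character).
#' @param probes a \linkS4class{ProbeTable} or path to a probe table.
#' @param coding coding \linkS4class{TranscriptSet}(s) or BED12 path(s);
#'   several sources may be given as a list.
#' @param lncrna lncRNA \linkS4class{TranscriptSet} or BED12 path.
#' @param params an \linkS4class{ArrayParams}.
#' @return a list with elements \code{annotation}
#'   (\linkS4class{LncAnnotation}), \code{clusterSet} (pre-pruning
#'   \linkS4class{ClusterSet}), \code{summary} (named integer vector of
#'   stage-wise counts) and \code{mask} (the coding-exon mask).
#' @export
buildAnnotationPipeline <- function(genome, probes, coding, lncrna,
                                    params = ArrayParams()) {
  if (is.character(probes)) probes <- readProbeTable(probes, params)
  if (is.character(lncrna)) lncrna <- readTranscriptsBed12(lncrna, "lncRNA")
  if (is(coding, "TranscriptSet")) coding <- list(coding)
  if (is.character(coding)) coding <- as.list(coding)
  coding <- lapply(coding, function(x)
    if (is.character(x)) readTranscriptsBed12(x, "coding") else x)

  index <- buildKmerIndex(genome, params)
  probes <- mapProbes(probes, index)
  mask <- codingExonMask(coding)
  probes <- filterProbesCoding(probes, mask, onlyPlaced = TRUE)
  lncKept <- filterShortLncrnas(lncrna, params)
  cs <- clusterTranscripts(lncKept)
  candidates <- segmentProbesets(cs)
  annotation <- assignProbes(probes, cs, candidates, params)

  st <- probeStatus(probeTable(annotation))
  summary <- c(
    total_probes = length(st),
    unmapped = sum(st == "unmapped"),
    multimapped = sum(st == "multimapped"),
    uniquely_mapped = sum(!(st %in% c("unmapped", "multimapped"))),
    protein_coding_probes = sum(st == "coding_overlap"),
    probes_matching_lncrnas = sum(st == "assigned"),
    probe_sets = length(probesetRanges(annotation)),
    transcript_clusters = length(clusterRanges(annotation)),
    lncrna_transcripts = length(annotation@transcripts),
    lncrna_input = length(lncrna),
    lncrna_after_length_filter = length(lncKept))
  list(annotation = annotation, clusterSet = cs, summary = summary,
       mask = mask)
}

#' Run the expression analysis on an annotation
#'
#' Linear probe intensities are quantile-normalized, then summarized by
#' median polish at the probe-set level and at the cluster level (the
#' cluster signal pools all retained probes of the cluster, not the mean
#' of probe-set summaries), GNI and Splice Index are computed per probe
#' set, and cluster-level differential expression per cluster.
#'
#' @param annotation an \linkS4class{LncAnnotation}.
#' @param intensities linear probe intensity matrix (or path to its TSV);
#'   must contain every assigned probe of the annotation.
#' @param design named factor from \code{\link{groupDesign}} (or path to a
#'   design TSV).
#' @param fcThreshold,siThreshold,fdrThreshold thresholds for the filtered
#'   convenience report (defaults: |log2 fc| > 1, |SI| > 1, FDR < 0.05).
#' @return a list with \code{probesetExpr}, \code{clusterExpr} (log2
#'   matrices), \code{gni}, \code{splice}, \code{de} (result data frames)
#'   and \code{report} (filtered DE / splice hits).
#' @export
analyzeExpression <- function(annotation, intensities, design,
                              fcThreshold = 1, siThreshold = 1,
                              fdrThreshold = 0.05) {
  stopifnot(is(annotation, "LncAnnotation"))
  if (is.character(intensities))
    intensities <- readExpressionMatrix(intensities)
  if (is.character(design)) design <- readGroupDesign(design)
  if (!all(names(design) %in% colnames(intensities)))
    stop("design references unknown samples: ",
         paste(setdiff(names(design), colnames(intensities)),
               collapse = ", "))
  intensities <- intensities[, names(design), drop = FALSE]

  pToPs <- probeToProbeset(annotation)
  psToCl <- probesetToCluster(annotation)
  pToCl <- stats::setNames(unname(psToCl[pToPs]), names(pToPs))
  norm <- quantileNormalize(intensities)
  psExpr <- summarizeByFeature(norm, pToPs,
                               featureOrder = names(psToCl))
  clExpr <- summarizeByFeature(norm, pToCl,
                               featureOrder = unique(unname(psToCl)))
  gni <- computeGNI(psExpr, clExpr, psToCl)
  splice <- spliceIndex(gni, design, psToCl)
  de <- differentialExpression(clExpr, design)
  report <- list(
    de_hits = de[abs(de$log2_fold_change) > fcThreshold &
                   de$fdr < fdrThreshold, , drop = FALSE],
    splice_hits = splice[abs(splice$si) > siThreshold &
                           splice$fdr < fdrThreshold, , drop = FALSE])
  list(probesetExpr = psExpr, clusterExpr = clExpr, gni = gni,
       splice = splice, de = de, report = report)
}

#' Write the expression-analysis result files
#'
#' Emits \code{cluster_expression.tsv}, \code{probeset_expression.tsv},
#' \code{gni.tsv}, \code{splice_results.tsv} and \code{de_results.tsv}.
#'
#' @param results list from \code{\link{analyzeExpression}}.
#' @param outdir output directory (created if needed).
#' @return named vector of file paths, invisibly.
#' @export
writeAnalysisFiles <- function(results, outdir) {
  if (!dir.exists(outdir) &&
      !dir.create(outdir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", outdir)
  paths <- c(cluster_expression = file.path(outdir, "cluster_expression.tsv"),
             probeset_expression = file.path(outdir,
                                             "probeset_expression.tsv"),
             gni = file.path(outdir, "gni.tsv"),
             splice = file.path(outdir, "splice_results.tsv"),
             de = file.path(outdir, "de_results.tsv"))
  writeExpressionMatrix(results$clusterExpr, paths[["cluster_expression"]],
                        idColumn = "cluster_id")
  writeExpressionMatrix(results$probesetExpr,
                        paths[["probeset_expression"]],
                        idColumn = "probeset_id")
  writeExpressionMatrix(results$gni, paths[["gni"]],
                        idColumn = "probeset_id")
  utils::write.table(results$splice, paths[["splice"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(results$de, paths[["de"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paths)
}

#' Generate a complete synthetic test workspace
#'
#' Writes a toy genome (FASTA), coding and lncRNA transcript models
#' (BED12), a probe table (TSV), a two-group design and a simulated
#' intensity matrix with one planted differential probe set (splice
#' effect) and one planted differentially expressed cluster, then returns
#' the paths together with the generating truth.
#'
#' @param dir output directory.
#' @param seed integer seed driving every generator.
#' @param nSamples samples per group.
#' @param spliceDelta planted probe-set effect (log2).
#' @param deDelta planted cluster effect (log2).
#' @param tau,sigma probe-affinity and noise standard deviations.
#' @param ... passed to \code{\link{makeTranscriptome}}.
#' @return a list with \code{paths} (named vector), \code{truth} (planted
#'   effects and probe classes) and \code{annotation} (the
#'   \linkS4class{LncAnnotation} the simulation used).
#' @export
makeFixtureWorkspace <- function(dir, seed, nSamples = 5L,
                                 spliceDelta = 2, deDelta = 3,
                                 tau = 0.5, sigma = 0.25, ...) {
  if (!dir.exists(dir) &&
      !dir.create(dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create directory: ", dir)
  params <- ArrayParams()
  genome <- makeToyGenome(seed)
  txs <- makeTranscriptome(seed + 1L, genome, ...)
  pt <- makeProbeTable(seed + 2L, genome, txs, params = params)
  coding <- txs[which(txBiotype(txs) == "coding")]
  lncrna <- txs[which(txBiotype(txs) == "lncRNA")]

  paths <- c(genome = file.path(dir, "genome.fa"),
             probes = file.path(dir, "probes.tsv"),
             coding = file.path(dir, "coding.bed"),
             lncrna = file.path(dir, "lncrna.bed"),
             intensities = file.path(dir, "intensities.tsv"),
             design = file.path(dir, "design.tsv"))
  Biostrings::writeXStringSet(genome, paths[["genome"]])
  writeProbeTable(pt$probes, paths[["probes"]])
  writeTranscriptsBed12(coding, paths[["coding"]])
  writeTranscriptsBed12(lncrna, paths[["lncrna"]])

  built <- buildAnnotationPipeline(genome, pt$probes, coding, lncrna,
                                   params)
  annotation <- built$annotation
  design <- groupDesign(
    paste0("S", seq_len(2L * nSamples)),
    rep(c("A", "B"), each = nSamples))
  utils::write.table(
    data.frame(sample_id = names(design), group = as.character(design)),
    paths[["design"]], sep = "\t", quote = FALSE, row.names = FALSE)

  ps <- probesetRanges(annotation)
  cl <- clusterRanges(annotation)
  multi <- names(which(table(ps$cluster_id) >= 3L))
  spliceTarget <- if (length(multi))
    ps$probeset_id[ps$cluster_id == multi[1L]][1L] else ps$probeset_id[1L]
  deCandidates <- setdiff(cl$cluster_id,
                          ps$cluster_id[ps$probeset_id == spliceTarget])
  deTarget <- deCandidates[length(deCandidates)]
  spliceEffects <- data.frame(probeset_id = spliceTarget,
                              delta = spliceDelta, group = "A")
  deEffects <- data.frame(cluster_id = deTarget, delta = deDelta,
                          group = "A")
  inten <- simulateIntensities(seed + 3L, annotation, design,
                               spliceEffects = spliceEffects,
                               deEffects = deEffects,
                               tau = tau, sigma = sigma)
  writeExpressionMatrix(inten, paths[["intensities"]],
                        idColumn = "probe_id")
  list(paths = paths,
       truth = list(probeClasses = pt$truth,
                    spliceEffects = spliceEffects,
                    deEffects = deEffects,
                    summary = built$summary),
       annotation = annotation,
       design = design)
}
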