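## The core of the custom annotation: length filter, coding-exon mask and
## probe exclusion, same-strand transcript clustering, probe-set
## segmentation at exon boundaries, probe assignment and pruning.

#' Discard short lncRNAs
#'
#' Removes non-coding transcripts whose spliced length (sum of exon
#' lengths, not genomic span) is 200 nt or shorter; i.e. keeps transcripts
#' with spliced length of at least \code{minSplicedLength} (default 201).
#'
#' @param ts a \linkS4class{TranscriptSet} of lncRNAs.
#' @param params an \linkS4class{ArrayParams}.
#' @return the filtered \linkS4class{TranscriptSet}, order preserved.
#' @export
filterShortLncrnas <- function(ts, params = ArrayParams()) {
  stopifnot(is(ts, "TranscriptSet"))
  if (length(ts) == 0L) return(ts)
  if (!all(txBiotype(ts) == "lncRNA"))
    stop("filterShortLncrnas expects lncRNA transcripts")
  ts[splicedLength(ts) >= params@minSplicedLength]
}

#' Build the coding-exon mask
#'
#' The union of all exons of all protein-coding transcripts from one or
#' more annotation sources, merged maximally per (chromosome, strand).
#' Probes overlapping this mask on the same strand are excluded.
#'
#' @param ... one or more \linkS4class{TranscriptSet}s of biotype
#'   \code{coding} (e.g. different annotation sources).
#' @return a strand-aware \code{GRanges} of merged disjoint intervals.
#' @export
codingExonMask <- function(...) {
  sets <- list(...)
  if (length(sets) == 1L && is.list(sets[[1L]]) &&
      !is(sets[[1L]], "TranscriptSet"))
    sets <- sets[[1L]]
  ex <- lapply(sets, function(ts) {
    stopifnot(is(ts, "TranscriptSet"))
    if (length(ts) && !all(txBiotype(ts) == "coding"))
      stop("codingExonMask expects coding transcripts only")
    unlist(exonRanges(ts), use.names = FALSE)
  })
  all <- do.call(c, c(ex, list(GRanges())))
  mcols(all) <- NULL
  sort(reduce(all))          # reduce() is strand-aware: one mask per strand
}

#' Exclude probes overlapping coding exons
#'
#' A uniquely mapped probe whose alignment overlaps any coding-mask
#' interval on the same strand by at least 1 bp is marked
#' \code{coding_overlap}. Probes aligned opposite-strand to a coding exon,
#' or inside a coding intron, are retained.
#'
#' @param probes a \linkS4class{ProbeTable}; all probes must be placed and
#'   unassigned (run after \code{\link{mapProbes}} on the uniquely mapped
#'   subset, or pass the full table with \code{onlyPlaced = TRUE}).
#' @param mask coding-exon mask from \code{\link{codingExonMask}}.
#' @param onlyPlaced if \code{TRUE}, unmapped/multimapped probes are passed
#'   through untouched instead of raising an error.
#' @return the updated \linkS4class{ProbeTable}.
#' @export
filterProbesCoding <- function(probes, mask, onlyPlaced = FALSE) {
  stopifnot(is(probes, "ProbeTable"), is(mask, "GRanges"))
  d <- probeData(probes)
  placed <- d$status == "unassigned"
  if (!onlyPlaced && !all(placed))
    stop("filterProbesCoding applies only to uniquely placed probes ",
         "(status 'unassigned'); got other statuses")
  if (!any(placed)) return(probes)
  aln <- GRanges(d$chrom[placed], IRanges(d$start[placed], d$end[placed]),
                 strand = d$strand[placed])
  hit <- overlapsAny(aln, mask)   # strand-aware by default
  updateProbes(probes, which(placed)[hit], status = "coding_overlap")
}

#' Cluster lncRNAs overlapping on the same strand
#'
#' Transcript clusters are the connected components of the graph whose
#' nodes are transcripts and whose edges join same-strand pairs sharing at
#' least 1 bp of exon (overlap is exon-level, not span-level, so nested
#' neighbours that share no transcribed sequence stay separate). Cluster
#' ids are deterministic: clusters are sorted by (chromosome, strand, span
#' start) and numbered.
#'
#' @param ts a \linkS4class{TranscriptSet} of lncRNAs.
#' @return a \linkS4class{ClusterSet}.
#' @export
clusterTranscripts <- function(ts) {
  stopifnot(is(ts, "TranscriptSet"))
  if (length(ts) && !all(txBiotype(ts) == "lncRNA"))
    stop("clusterTranscripts expects lncRNA transcripts")
  n <- length(ts)
  if (n == 0L)
    return(new("ClusterSet", transcripts = ts, clusterId = character(0),
               clusters = GRanges(cluster_id = character(0),
                                  n_transcripts = integer(0))))
  exl <- exonRanges(ts)
  flat <- unlist(exl, use.names = FALSE)
  txOf <- rep(seq_len(n), elementNROWS(exl))
  ## strand-aware merged exon blocks; min.gapwidth = 0 keeps abutting
  ## exons apart: clustering requires >= 1 bp of shared sequence
  red <- reduce(flat, min.gapwidth = 0L)
  ov <- findOverlaps(flat, red)
  ## union-find: transcripts touching the same merged block are connected
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  grp <- split(txOf[queryHits(ov)], subjectHits(ov))
  for (g in grp) {
    g <- unique(g)
    if (length(g) > 1L) {
      r <- find(g[1L])
      for (j in g[-1L]) {
        rj <- find(j)
        if (rj != r) parent[rj] <- r
      }
    }
  }
  comp <- vapply(seq_len(n), find, integer(1))
  spans <- txSpans(ts)
  cchrom <- vapply(split(as.character(seqnames(spans)), comp),
                   `[`, character(1), 1L)
  cstrand <- vapply(split(as.character(strand(spans)), comp),
                    `[`, character(1), 1L)
  cstart <- vapply(split(start(spans), comp), min, integer(1))
  cend <- vapply(split(end(spans), comp), max, integer(1))
  ntx <- lengths(split(comp, comp))
  ord <- order(cchrom, factor(cstrand, c("+", "-")), cstart, cend)
  ids <- sprintf("CL%05d", seq_along(ord))
  compKeys <- names(cchrom)[ord]
  idOfComp <- stats::setNames(ids, compKeys)
  clusterId <- unname(idOfComp[as.character(comp)])
  clusters <- GRanges(cchrom[ord], IRanges(cstart[ord], cend[ord]),
                      strand = cstrand[ord])
  mcols(clusters) <- DataFrame(cluster_id = ids,
                               n_transcripts = as.integer(ntx[ord]))
  names(clusters) <- ids
  new("ClusterSet", transcripts = ts, clusterId = clusterId,
      clusters = clusters)
}

#' Segment transcript clusters into probe sets
#'
#' Within each cluster, probe sets are the maximal sub-intervals of the
#' exonic footprint (union of all member exons) whose interiors contain no
#' exon boundary of any member transcript: contiguous regions not
#' interrupted by exon boundaries. Output is sorted by start within each
#' cluster; probe-set ids are \code{<cluster_id>_PS<ordinal>}.
#'
#' @param cs a \linkS4class{ClusterSet}.
#' @return a \code{GRanges} of candidate probe sets with metadata columns
#'   \code{probeset_id}, \code{cluster_id} (no probes assigned yet).
#' @export
segmentProbesets <- function(cs) {
  stopifnot(is(cs, "ClusterSet"))
  memb <- unname(cs@clusterId)
  exl <- exonRanges(cs@transcripts)
  flat <- unlist(exl, use.names = FALSE)
  exOf <- rep(memb, elementNROWS(exl))
  ids <- cs@clusters$cluster_id
  segStart <- integer(0); segEnd <- integer(0)
  segCluster <- character(0); segId <- character(0)
  chromOf <- as.character(seqnames(cs@clusters))
  strandOf <- as.character(strand(cs@clusters))
  names(chromOf) <- names(strandOf) <- ids
  for (id in ids) {
    segs <- cutAtBoundaries(ranges(flat)[exOf == id])
    segStart <- c(segStart, start(segs))
    segEnd <- c(segEnd, end(segs))
    segCluster <- c(segCluster, rep(id, length(segs)))
    segId <- c(segId, sprintf("%s_PS%03d", id, seq_along(segs)))
  }
  ans <- GRanges(chromOf[segCluster], IRanges(segStart, segEnd),
                 strand = strandOf[segCluster])
  mcols(ans) <- DataFrame(probeset_id = segId, cluster_id = segCluster)
  names(ans) <- segId
  ans
}

## internal: cut the covered footprint of `ir` (IRanges) at every exon
## start/end, returning maximal constant segments.
cutAtBoundaries <- function(ir) {
  foot <- reduce(ir)
  if (length(foot) == 0L) return(IRanges())
  bp <- sort(unique(c(start(ir), end(ir) + 1L)))
  starts <- integer(0)
  ends <- integer(0)
  for (i in seq_along(foot)) {
    s <- start(foot)[i]; e <- end(foot)[i]
    cuts <- bp[bp > s & bp <= e]
    ss <- c(s, cuts)
    ee <- c(cuts - 1L, e)
    starts <- c(starts, ss)
    ends <- c(ends, ee)
  }
  IRanges(starts, ends)
}

#' Assign probes to probe sets and prune
#'
#' A probe is assigned to a probe set iff its alignment is fully contained
#' in the probe-set interval on the same strand; probes straddling a
#' probe-set boundary stay unassigned. Probe sets retaining fewer than
#' \code{minProbesPerSet} probes (default: any probes at all) are deleted,
#' and clusters left without probe sets are deleted in turn.
#'
#' @param probes a \linkS4class{ProbeTable} after the coding filter.
#' @param cs the \linkS4class{ClusterSet} the probe sets came from.
#' @param probesets candidate probe sets from
#'   \code{\link{segmentProbesets}}.
#' @param params an \linkS4class{ArrayParams}.
#' @return an \linkS4class{LncAnnotation}.
#' @export
assignProbes <- function(probes, cs, probesets, params = ArrayParams()) {
  stopifnot(is(probes, "ProbeTable"), is(cs, "ClusterSet"),
            is(probesets, "GRanges"))
  d <- probeData(probes)
  cand <- which(d$status == "unassigned")
  if (length(cand)) {
    aln <- GRanges(d$chrom[cand], IRanges(d$start[cand], d$end[cand]),
                   strand = d$strand[cand])
    ov <- findOverlaps(aln, probesets, type = "within")
    if (any(countQueryHits(ov) > 1L))
      stop("internal consistency error: a probe is contained in more ",
           "than one probe set")
    probes <- updateProbes(probes, cand[queryHits(ov)],
                           status = "assigned",
                           probeset_id = probesets$probeset_id[subjectHits(ov)])
  }
  d <- probeData(probes)
  nProbes <- table(factor(d$probeset_id[d$status == "assigned"],
                          levels = probesets$probeset_id))
  keepPs <- as.integer(nProbes) >= params@minProbesPerSet
  ps <- probesets[keepPs]
  ps$n_probes <- as.integer(nProbes[keepPs])
  keptClusters <- unique(ps$cluster_id)
  cl <- cs@clusters[cs@clusters$cluster_id %in% keptClusters]
  cl$n_probesets <- as.integer(table(factor(ps$cluster_id,
                                            cl$cluster_id)))
  clProbes <- tapply(ps$n_probes, factor(ps$cluster_id, cl$cluster_id), sum)
  cl$n_probes <- as.integer(clProbes)
  keepTx <- cs@clusterId %in% keptClusters
  new("LncAnnotation",
      clusters = cl,
      probesets = ps,
      probes = probes,
      transcripts = cs@transcripts[which(keepTx)],
      membership = cs@clusterId[keepTx])
}

## ---- LncAnnotation accessors ----

#' @rdname clusterRanges
#' @export
setMethod("clusterRanges", "LncAnnotation", function(object) object@clusters)

#' @rdname probesetRanges
#' @export
setMethod("probesetRanges", "LncAnnotation", function(object)
  object@probesets)

#' @rdname probeTable
#' @export
setMethod("probeTable", "LncAnnotation", function(object) object@probes)

#' @rdname clusterMembership
#' @export
setMethod("clusterMembership", "LncAnnotation", function(object) {
  out <- object@membership
  names(out) <- txId(object@transcripts)
  out
})

setMethod("show", "LncAnnotation", function(object) {
  cat("LncAnnotation\n",
      "  transcript clusters: ", length(object@clusters), "\n",
      "  probe sets:          ", length(object@probesets), "\n",
      "  lncRNA transcripts:  ", length(object@transcripts), "\n",
      "  probes assigned:     ",
      sum(probeData(object@probes)$status == "assigned"), "\n", sep = "")
})

#' Probe-set to cluster mapping
#' @param annotation an \linkS4class{LncAnnotation}.
#' @return named character vector: cluster id per probe-set id.
#' @export
probesetToCluster <- function(annotation) {
  stopifnot(is(annotation, "LncAnnotation"))
  stats::setNames(annotation@probesets$cluster_id,
                  annotation@probesets$probeset_id)
}

#' Probe to probe-set mapping
#' @param annotation an \linkS4class{LncAnnotation}.
#' @return named character vector over assigned probes: probe-set id per
#'   probe id.
#' @export
probeToProbeset <- function(annotation) {
  d <- probeData(probeTable(annotation))
  d <- d[d$status == "assigned", ]
  stats::setNames(d$probeset_id, d$probe_id)
}
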