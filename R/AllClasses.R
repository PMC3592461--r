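#' @import methods
#' @import S4Vectors
#' @import IRanges
#' @import GenomicRanges
NULL

PROBE_STATUSES <- c("unmapped", "multimapped", "coding_overlap",
                    "unassigned", "assigned")

#' Analysis parameters
#'
#' Holds the tunable parameters of the annotation pipeline: the probe length
#' of the array platform, the minimum spliced length for a lncRNA to be
#' retained (transcripts of 200 nt or shorter are discarded, i.e. the
#' default keeps spliced lengths of at least 201 nt), the distance below
#' which a non-overlapping cluster counts as proximate to a protein-coding
#' gene, and the minimum number of probes a probe set must retain.
#'
#' @slot probeLength integer, probe length in nt (platform constant, 25).
#' @slot minSplicedLength integer, minimum spliced length in bp a lncRNA
#'   must reach to be kept (default 201, i.e. strictly longer than 200 nt).
#' @slot proximateDistance integer, bp; gaps strictly smaller than this
#'   make a neighbouring gene "proximate" (default 1000).
#' @slot minProbesPerSet integer, probe sets with fewer probes are pruned
#'   (default 1: only empty probe sets are deleted).
#' @export
setClass("ArrayParams", representation(
  probeLength = "integer",
  minSplicedLength = "integer",
  proximateDistance = "integer",
  minProbesPerSet = "integer"
))

setValidity("ArrayParams", function(object) {
  v <- c(probeLength = object@probeLength,
         minSplicedLength = object@minSplicedLength,
         proximateDistance = object@proximateDistance,
         minProbesPerSet = object@minProbesPerSet)
  if (any(is.na(v)) || any(v < 1L))
    return("all parameters must be positive integers")
  TRUE
})

#' Construct an ArrayParams object
#'
#' @param probeLength probe length in nt.
#' @param minSplicedLength minimum lncRNA spliced length in bp to keep.
#' @param proximateDistance proximity threshold in bp for positional
#'   classification.
#' @param minProbesPerSet minimum probes per surviving probe set.
#' @return an \linkS4class{ArrayParams} object.
#' @examples
#' ArrayParams()
#' @export
ArrayParams <- function(probeLength = 25L, minSplicedLength = 201L,
                        proximateDistance = 1000L, minProbesPerSet = 1L) {
  new("ArrayParams",
      probeLength = as.integer(probeLength),
      minSplicedLength = as.integer(minSplicedLength),
      proximateDistance = as.integer(proximateDistance),
      minProbesPerSet = as.integer(minProbesPerSet))
}

setMethod("show", "ArrayParams", function(object) {
  cat("ArrayParams\n",
      "  probeLength:       ", object@probeLength, " nt\n",
      "  minSplicedLength:  ", object@minSplicedLength, " bp\n",
      "  proximateDistance: ", object@proximateDistance, " bp\n",
      "  minProbesPerSet:   ", object@minProbesPerSet, "\n", sep = "")
})

#' Set of exon-structured transcript models
#'
#' A container for transcript models: each transcript is an ordered set of
#' exons on one chromosome and strand, with a biotype of either
#' \code{"coding"} or \code{"lncRNA"}. Exons are stored as a
#' \code{GRangesList} (one element per transcript) whose metadata columns
#' carry \code{tx_id}, \code{accession} and \code{biotype}.
#'
#' @slot exons a \code{CompressedGRangesList}, one element per transcript;
#'   exons sorted, disjoint, all on the transcript's chromosome and strand.
#' @export
setClass("TranscriptSet", representation(exons = "CompressedGRangesList"))

setValidity("TranscriptSet", function(object) {
  ex <- object@exons
  md <- mcols(ex)
  need <- c("tx_id", "accession", "biotype")
  if (!all(need %in% colnames(md)))
    return(paste("exon GRangesList must carry metadata columns:",
                 paste(need, collapse = ", ")))
  if (anyDuplicated(md$tx_id))
    return("duplicated tx_id")
  if (!all(md$biotype %in% c("coding", "lncRNA")))
    return("biotype must be 'coding' or 'lncRNA'")
  if (length(ex)) {
    if (any(elementNROWS(ex) == 0L))
      return("every transcript must have at least one exon")
    flat <- unlist(ex, use.names = FALSE)
    if (length(flat) && min(start(flat)) < 1L)
      return("coordinates must be >= 1")
    grp <- rep(seq_along(ex), elementNROWS(ex))
    chr <- as.integer(seqnames(flat))
    str <- as.integer(strand(flat))
    if (any(as.character(strand(flat)) == "*"))
      return("strand must be '+' or '-'")
    sameTx <- grp[-1L] == grp[-length(grp)]
    if (length(flat) > 1L) {
      if (any(sameTx & (chr[-1L] != chr[-length(chr)] |
                        str[-1L] != str[-length(str)])))
        return("exons of one transcript must share chromosome and strand")
      ## sorted by start and pairwise disjoint in one sweep
      if (any(sameTx & start(flat)[-1L] <= end(flat)[-length(flat)]))
        return("exons must be pairwise disjoint and sorted by start")
    }
  }
  TRUE
})

#' Construct a TranscriptSet
#'
#' @param exons a \code{GRangesList} (or list of \code{GRanges}), one
#'   element per transcript. Exons are sorted by start on construction.
#' @param txId character vector of transcript identifiers.
#' @param accession character vector of source accessions (defaults to
#'   \code{txId}).
#' @param biotype \code{"coding"} or \code{"lncRNA"}, recycled.
#' @return a \linkS4class{TranscriptSet}.
#' @examples
#' gr <- GenomicRanges::GRanges("chr1",
#'   IRanges::IRanges(c(101, 301), c(150, 400)), strand = "+")
#' ts <- TranscriptSet(GenomicRanges::GRangesList(gr), txId = "T1",
#'                     biotype = "lncRNA")
#' splicedLength(ts)
#' @export
TranscriptSet <- function(exons, txId, accession = txId, biotype) {
  if (is.list(exons))
    exons <- GRangesList(exons)
  exons <- as(exons, "CompressedGRangesList")
  if (length(exons)) {
    ## sort exons by start within each transcript (vectorised)
    flat <- unlist(exons, use.names = FALSE)
    grp <- rep(seq_along(exons), elementNROWS(exons))
    ord <- order(grp, start(flat))
    if (is.unsorted(ord, strictly = TRUE)) {
      part <- PartitioningByEnd(grp, NG = length(exons))
      exons <- relist(flat[ord], part)
    }
  }
  mcols(exons) <- DataFrame(
    tx_id = as.character(txId),
    accession = as.character(accession),
    biotype = rep_len(as.character(biotype), length(exons)))
  names(exons) <- mcols(exons)$tx_id
  new("TranscriptSet", exons = exons)
}

#' Probe table with mapping state
#'
#' Holds the probes of the array with their sequences and, as the pipeline
#' progresses, their genomic alignment and assignment status. Status values
#' are \code{unmapped} (no genomic hit, or not yet mapped),
#' \code{multimapped} (more than one hit, discarded),
#' \code{coding_overlap} (uniquely mapped but overlapping a protein-coding
#' exon on the same strand, excluded), \code{unassigned} (uniquely mapped,
#' surviving the coding filter, not yet or never assigned to a probe set)
#' and \code{assigned}. Alignments are stored 1-based inclusive, the native
#' convention of \code{GRanges}.
#'
#' @slot data a \code{DataFrame} with columns \code{probe_id},
#'   \code{sequence}, \code{chrom}, \code{start}, \code{end},
#'   \code{strand}, \code{status}, \code{probeset_id}; alignment columns
#'   are \code{NA} for probes without a unique placement.
#' @export
setClass("ProbeTable", representation(data = "DFrame"))

setValidity("ProbeTable", function(object) {
  d <- object@data
  need <- c("probe_id", "sequence", "chrom", "start", "end", "strand",
            "status", "probeset_id")
  if (!all(need %in% colnames(d)))
    return(paste("missing columns:", paste(setdiff(need, colnames(d)),
                                           collapse = ", ")))
  if (anyDuplicated(d$probe_id))
    return("duplicated probe_id")
  if (!all(d$status %in% PROBE_STATUSES))
    return(paste("status must be one of:",
                 paste(PROBE_STATUSES, collapse = ", ")))
  placed <- !(d$status %in% c("unmapped", "multimapped"))
  if (any(placed & is.na(d$start)))
    return("placed probes must carry an alignment")
  if (any(!placed & !is.na(d$start)))
    return("unmapped/multimapped probes must not carry an alignment")
  if (any(placed) &&
      !all(d$end[placed] - d$start[placed] + 1L == nchar(d$sequence[placed])))
    return("alignment length must equal probe length")
  if (!all(is.na(d$probeset_id) == (d$status != "assigned")))
    return("probeset_id present iff status is 'assigned'")
  TRUE
})

#' Construct a ProbeTable
#'
#' @param probeId character vector of unique probe identifiers.
#' @param sequence character vector of probe sequences (uppercase ACGT).
#' @param chrom,start,end,strand optional alignment columns (1-based
#'   inclusive coordinates); \code{NA} where no unique alignment exists.
#' @param status probe status vector (default \code{"unmapped"}).
#' @param probesetId probe-set assignment (default \code{NA}).
#' @return a \linkS4class{ProbeTable}.
#' @export
ProbeTable <- function(probeId, sequence,
                       chrom = NA_character_, start = NA_integer_,
                       end = NA_integer_, strand = NA_character_,
                       status = "unmapped", probesetId = NA_character_) {
  n <- length(probeId)
  d <- DataFrame(
    probe_id = as.character(probeId),
    sequence = toupper(as.character(sequence)),
    chrom = rep_len(as.character(chrom), n),
    start = rep_len(as.integer(start), n),
    end = rep_len(as.integer(end), n),
    strand = rep_len(as.character(strand), n),
    status = rep_len(as.character(status), n),
    probeset_id = rep_len(as.character(probesetId), n))
  new("ProbeTable", data = d)
}

#' Exact-match k-mer index of a genome
#'
#' A hash-style lookup from every ungapped genome window of length k (the
#' probe length) to its placements. Only forward-strand windows are stored;
#' a query for a probe looks up the probe sequence (forward-strand hits)
#' and its reverse complement (reverse-strand hits), so a k-mer and its
#' reverse complement resolve to the same placements with strands mirrored.
#' Windows containing any non-ACGT character are skipped.
#'
#' @slot k integer word length (= probe length).
#' @slot words character vector of the distinct indexed k-mers.
#' @slot buckets list parallel to \code{words}; each element holds integer
#'   indices into \code{chrom}/\code{start} for that word's placements.
#' @slot chrom,start placement vectors (1-based forward-strand starts).
#' @slot seqLengths named integer vector of chromosome lengths.
#' @export
setClass("KmerIndex", representation(
  k = "integer",
  words = "character",
  buckets = "list",
  chrom = "character",
  start = "integer",
  seqLengths = "integer"
))

setValidity("KmerIndex", function(object) {
  if (length(object@words) != length(object@buckets))
    return("words and buckets must be parallel")
  if (length(object@chrom) != length(object@start))
    return("chrom and start must be parallel")
  if (length(object@start) &&
      any(object@start < 1L |
          object@start > object@seqLengths[object@chrom] - object@k + 1L))
    return("placement outside chromosome bounds")
  TRUE
})

setMethod("show", "KmerIndex", function(object) {
  cat("KmerIndex: k =", object@k, "|",
      length(object@words), "distinct words |",
      length(object@start), "placements |",
      length(object@seqLengths), "sequence(s)\n")
})

#' Transcript clusters of overlapping lncRNAs
#'
#' The gene-level units of the custom annotation: connected components of
#' the graph joining same-strand transcripts that share at least 1 bp of
#' exon. Produced by \code{\link{clusterTranscripts}}.
#'
#' @slot transcripts the clustered \linkS4class{TranscriptSet}.
#' @slot clusterId character vector parallel to the transcripts giving each
#'   transcript's cluster.
#' @slot clusters \code{GRanges} of cluster spans (min exon start to max
#'   exon end) with metadata columns \code{cluster_id},
#'   \code{n_transcripts}.
#' @export
setClass("ClusterSet", representation(
  transcripts = "TranscriptSet",
  clusterId = "character",
  clusters = "GRanges"
))

setValidity("ClusterSet", function(object) {
  if (length(object@clusterId) != length(object@transcripts@exons))
    return("clusterId must be parallel to transcripts")
  if (!all(object@clusterId %in% object@clusters$cluster_id))
    return("clusterId refers to unknown cluster")
  TRUE
})

#' Final custom lncRNA annotation
#'
#' The two-level annotation after probe assignment and pruning: transcript
#' clusters (gene level), probe sets (exon level), the full probe table
#' with final statuses, and the member transcripts of the retained
#' clusters. Probe sets without probes, and clusters without probe sets,
#' have been deleted.
#'
#' @slot clusters \code{GRanges} of retained cluster spans
#'   (\code{cluster_id}, \code{n_transcripts}, \code{n_probesets},
#'   \code{n_probes}).
#' @slot probesets \code{GRanges} of retained probe sets
#'   (\code{probeset_id}, \code{cluster_id}, \code{n_probes}).
#' @slot probes the full \linkS4class{ProbeTable} with final statuses.
#' @slot transcripts \linkS4class{TranscriptSet} of lncRNAs in retained
#'   clusters.
#' @slot membership character vector parallel to \code{transcripts}:
#'   cluster of each transcript.
#' @export
setClass("LncAnnotation", representation(
  clusters = "GRanges",
  probesets = "GRanges",
  probes = "ProbeTable",
  transcripts = "TranscriptSet",
  membership = "character"
))

setValidity("LncAnnotation", function(object) {
  ps <- object@probesets
  cl <- object@clusters
  if (!all(ps$cluster_id %in% cl$cluster_id))
    return("probe set refers to unknown cluster")
  if (length(cl) && any(cl$n_probesets == 0L))
    return("clusters without probe sets must be pruned")
  if (length(ps) && any(ps$n_probes == 0L))
    return("probe sets without probes must be pruned")
  TRUE
})

## ---- generics ----

#' @rdname TranscriptSet
#' @param object,x a \code{TranscriptSet}.
#' @export
setGeneric("txId", function(object) standardGeneric("txId"))

#' @rdname TranscriptSet
#' @export
setGeneric("txAccession", function(object) standardGeneric("txAccession"))

#' @rdname TranscriptSet
#' @export
setGeneric("txBiotype", function(object) standardGeneric("txBiotype"))

#' @rdname TranscriptSet
#' @export
setGeneric("exonRanges", function(object) standardGeneric("exonRanges"))

#' @rdname TranscriptSet
#' @export
setGeneric("splicedLength", function(object) standardGeneric("splicedLength"))

#' @rdname ProbeTable
#' @param object,x a \code{ProbeTable}.
#' @export
setGeneric("probeIds", function(object) standardGeneric("probeIds"))

#' @rdname ProbeTable
#' @export
setGeneric("probeStatus", function(object) standardGeneric("probeStatus"))

#' @rdname ProbeTable
#' @export
setGeneric("probeAlignments", function(object) standardGeneric("probeAlignments"))

#' @rdname ProbeTable
#' @export
setGeneric("probeData", function(object) standardGeneric("probeData"))

#' Cluster spans of a ClusterSet or LncAnnotation
#' @param object a \code{ClusterSet} or \code{LncAnnotation}.
#' @return a \code{GRanges} of cluster spans.
#' @export
setGeneric("clusterRanges", function(object) standardGeneric("clusterRanges"))

#' Probe-set intervals of an LncAnnotation
#' @param object an \code{LncAnnotation}.
#' @return a \code{GRanges} of probe-set intervals.
#' @export
setGeneric("probesetRanges", function(object) standardGeneric("probesetRanges"))

#' Probe table of an LncAnnotation
#' @param object an \code{LncAnnotation}.
#' @return the \code{ProbeTable}.
#' @export
setGeneric("probeTable", function(object) standardGeneric("probeTable"))

#' Cluster membership of transcripts
#' @param object a \code{ClusterSet} or \code{LncAnnotation}.
#' @return named character vector: cluster id per transcript.
#' @export
setGeneric("clusterMembership",
           function(object) standardGeneric("clusterMembership"))
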