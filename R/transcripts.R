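## Accessors and methods for TranscriptSet / ClusterSet.

#' @rdname TranscriptSet
#' @export
setMethod("txId", "TranscriptSet", function(object)
  mcols(object@exons)$tx_id)

#' @rdname TranscriptSet
#' @export
setMethod("txAccession", "TranscriptSet", function(object)
  mcols(object@exons)$accession)

#' @rdname TranscriptSet
#' @export
setMethod("txBiotype", "TranscriptSet", function(object)
  mcols(object@exons)$biotype)

#' @rdname TranscriptSet
#' @export
setMethod("exonRanges", "TranscriptSet", function(object) object@exons)

#' @rdname TranscriptSet
#' @export
setMethod("splicedLength", "TranscriptSet", function(object) {
  out <- sum(width(object@exons))
  names(out) <- txId(object)
  out
})

#' @rdname TranscriptSet
#' @export
setMethod("length", "TranscriptSet", function(x) length(x@exons))

#' @rdname TranscriptSet
#' @param i index for subsetting.
#' @export
setMethod("[", "TranscriptSet", function(x, i) {
  if (is.character(i))
    i <- match(i, txId(x))
  initialize(x, exons = x@exons[i])
})

setMethod("show", "TranscriptSet", function(object) {
  bt <- table(factor(txBiotype(object), c("coding", "lncRNA")))
  cat("TranscriptSet:", length(object), "transcript(s) (",
      bt[["coding"]], "coding,", bt[["lncRNA"]], "lncRNA )\n")
  if (length(object)) {
    sl <- splicedLength(object)
    cat("  spliced length:", min(sl), "-", max(sl), "bp; exons per tx:",
        min(elementNROWS(object@exons)), "-",
        max(elementNROWS(object@exons)), "\n")
  }
})

#' Combine two TranscriptSets
#' @param x,... TranscriptSet objects.
#' @return a TranscriptSet with the transcripts of all arguments.
#' @export
setMethod("c", "TranscriptSet", function(x, ...) {
  args <- list(x, ...)
  ex <- do.call(c, lapply(args, function(a) a@exons))
  new("TranscriptSet", exons = ex)
})

#' Genomic span of each transcript
#'
#' @param object a \linkS4class{TranscriptSet}.
#' @return a \code{GRanges}, one range per transcript (min exon start to
#'   max exon end), with \code{tx_id} and \code{biotype} metadata.
#' @export
txSpans <- function(object) {
  stopifnot(is(object, "TranscriptSet"))
  ex <- object@exons
  flat <- unlist(ex, use.names = FALSE)
  p <- PartitioningByEnd(ex)
  i1 <- start(p)                 # exons are sorted and disjoint, so the
  i2 <- end(p)                   # span is first start to last end
  spans <- GRanges(seqnames(flat)[i1],
                   IRanges(start(flat)[i1], end(flat)[i2]),
                   strand = strand(flat)[i1])
  mcols(spans) <- DataFrame(tx_id = txId(object),
                            biotype = txBiotype(object))
  names(spans) <- txId(object)
  spans
}

## ---- ClusterSet ----

#' @rdname clusterRanges
#' @export
setMethod("clusterRanges", "ClusterSet", function(object) object@clusters)

#' @rdname clusterMembership
#' @export
setMethod("clusterMembership", "ClusterSet", function(object) {
  out <- object@clusterId
  names(out) <- txId(object@transcripts)
  out
})

#' @describeIn ClusterSet number of clusters.
#' @param x a \code{ClusterSet}.
#' @export
setMethod("length", "ClusterSet", function(x) length(x@clusters))

setMethod("show", "ClusterSet", function(object) {
  cat("ClusterSet:", length(object@clusters), "cluster(s) from",
      length(object@transcripts), "lncRNA transcript(s)\n")
})

#' Transcripts of a ClusterSet
#' @param object a \code{ClusterSet}.
#' @return the member \linkS4class{TranscriptSet}.
#' @export
clusterTxs <- function(object) {
  stopifnot(is(object, "ClusterSet"))
  object@transcripts
}
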