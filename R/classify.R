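## Positional classification of transcript clusters relative to
## protein-coding genes: seven disjoint categories, evaluated in the
## precedence order sense > antisense > intronic > bidirectional >
## extension > close > intergenic. "Proximate" means a gap strictly
## between 0 and proximateDistance bp (non-overlapping).

CLUSTER_CATEGORIES <- c("sense", "antisense", "intronic", "bidirectional",
                        "extension", "close", "intergenic")

#' Classify transcript clusters by position relative to coding genes
#'
#' Categories, in precedence order:
#' \describe{
#'   \item{sense}{cluster exons overlap coding exons on the same strand
#'     (>= 1 bp).}
#'   \item{antisense}{cluster exons overlap coding exons on the opposite
#'     strand.}
#'   \item{intronic}{cluster span lies entirely within one intron of a
#'     coding gene, with no exon overlap.}
#'   \item{bidirectional}{non-overlapping, opposite strand, 5' ends facing
#'     each other (head-to-head, divergent-promoter geometry), gap smaller
#'     than \code{proximateDistance}.}
#'   \item{extension}{non-overlapping, same strand, gap smaller than
#'     \code{proximateDistance}.}
#'   \item{close}{non-overlapping, opposite strand, gap smaller than
#'     \code{proximateDistance}, not head-to-head.}
#'   \item{intergenic}{everything else.}
#' }
#' The reported distance is the minimal gap between the cluster span and
#' the nearest gene span (0 when spans overlap). Gene spans are the union
#' of each gene's transcripts; without gene grouping every coding
#' transcript is its own gene.
#'
#' @param object a \linkS4class{ClusterSet} or \linkS4class{LncAnnotation}.
#' @param coding a \linkS4class{TranscriptSet} of coding transcripts.
#' @param params an \linkS4class{ArrayParams}.
#' @param geneId optional character vector parallel to \code{coding}
#'   grouping transcripts into genes.
#' @return a \code{data.frame} with columns \code{cluster_id},
#'   \code{category}, \code{nearest_gene}, \code{distance} (\code{NA} when
#'   no coding gene exists).
#' @export
classifyClusters <- function(object, coding, params = ArrayParams(),
                             geneId = NULL) {
  if (is(object, "LncAnnotation")) {
    spans <- clusterRanges(object)
    memb <- object@membership
    exl <- exonRanges(object@transcripts)
  } else if (is(object, "ClusterSet")) {
    spans <- clusterRanges(object)
    memb <- object@clusterId
    exl <- exonRanges(object@transcripts)
  } else stop("object must be a ClusterSet or LncAnnotation")
  stopifnot(is(coding, "TranscriptSet"))
  n <- length(spans)
  out <- data.frame(cluster_id = if (n) spans$cluster_id else character(0),
                    category = character(n),
                    nearest_gene = NA_character_,
                    distance = NA_integer_)
  if (n == 0L) return(out)
  if (length(coding) == 0L) {
    out$category <- "intergenic"
    return(out)
  }
  if (is.null(geneId))
    geneId <- txId(coding)
  codingSpans <- txSpans(coding)
  geneFac <- factor(geneId, unique(geneId))
  geneSpans <- unlist(range(split(codingSpans, geneFac)), use.names = FALSE)
  geneIds <- levels(geneFac)
  names(geneSpans) <- geneIds
  exByGene <- reduce(split(unlist(exonRanges(coding), use.names = FALSE),
                           rep(geneFac, elementNROWS(exonRanges(coding)))))
  introns <- psetdiff(geneSpans, exByGene)
  codingEx <- unlist(exByGene, use.names = FALSE)
  prox <- params@proximateDistance

  flipStrand <- function(gr) {
    strand(gr) <- ifelse(as.character(strand(gr)) == "+", "-", "+")
    gr
  }

  for (i in seq_len(n)) {
    S <- spans[i]
    cid <- S$cluster_id
    cex <- unlist(exl[memb == cid], use.names = FALSE)
    mcols(cex) <- NULL
    cex <- reduce(cex)

    gaps <- GenomicRanges::distance(rep(S, length(geneSpans)), geneSpans,
                                    ignore.strand = TRUE)
    spanOverlap <- overlapsAny(S, geneSpans, ignore.strand = TRUE)
    dist <- if (all(is.na(gaps))) NA_integer_ else {
      if (any(spanOverlap)) 0L else min(gaps, na.rm = TRUE)
    }
    nearest <- if (all(is.na(gaps))) NA_character_ else {
      if (any(spanOverlap)) geneIds[which(spanOverlap)[1L]]
      else geneIds[which.min(gaps)]
    }

    senseHit <- findOverlaps(cex, codingEx, ignore.strand = TRUE)
    sameStr <- as.character(strand(codingEx)[subjectHits(senseHit)]) ==
      as.character(strand(cex)[queryHits(senseHit)])
    pickGene <- function(exIdx) {
      g <- rep(geneIds, elementNROWS(exByGene))[exIdx]
      g[1L]
    }
    if (any(sameStr)) {
      out$category[i] <- "sense"
      out$nearest_gene[i] <- pickGene(subjectHits(senseHit)[sameStr])
      out$distance[i] <- 0L
      next
    }
    if (length(senseHit)) {           # remaining hits are opposite-strand
      out$category[i] <- "antisense"
      out$nearest_gene[i] <- pickGene(subjectHits(senseHit))
      out$distance[i] <- 0L
      next
    }
    intrHost <- NA_character_
    for (g in which(as.logical(overlapsAny(
      rep(S, length(geneSpans)), geneSpans, type = "within",
      ignore.strand = TRUE)))) {
      if (any(start(introns[[g]]) <= start(S) &
              end(introns[[g]]) >= end(S))) {
        intrHost <- geneIds[g]
        break
      }
    }
    if (!is.na(intrHost)) {
      out$category[i] <- "intronic"
      out$nearest_gene[i] <- intrHost
      out$distance[i] <- 0L
      next
    }
    cand <- which(!is.na(gaps) & gaps > 0L & gaps < prox & !spanOverlap)
    if (length(cand)) {
      cstr <- as.character(strand(S))
      gstr <- as.character(strand(geneSpans)[cand])
      clusterLeft <- end(S) < start(geneSpans)[cand]
      leftStr <- ifelse(clusterLeft, cstr, gstr)
      rightStr <- ifelse(clusterLeft, gstr, cstr)
      h2h <- (gstr != cstr) & leftStr == "-" & rightStr == "+"
      same <- gstr == cstr
      pick <- function(sel) cand[sel][which.min(gaps[cand][sel])]
      if (any(h2h)) {
        j <- pick(h2h)
        out$category[i] <- "bidirectional"
      } else if (any(same)) {
        j <- pick(same)
        out$category[i] <- "extension"
      } else {
        j <- pick(!same)
        out$category[i] <- "close"
      }
      out$nearest_gene[i] <- geneIds[j]
      out$distance[i] <- gaps[j]
      next
    }
    out$category[i] <- "intergenic"
    out$nearest_gene[i] <- nearest
    out$distance[i] <- dist
  }
  out
}
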