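## Readers/writers for the on-disk formats: BED12 transcripts, the probe
## table, expression matrices, the group design, and the emitted annotation
## file set. BED I/O goes through rtracklayer; all BED files are 0-based
## half-open on disk and GRanges (1-based inclusive) in memory.

#' Read transcript models from a BED12 file
#'
#' Exon structures are reconstructed from the BED block fields
#' (\code{blockCount}, \code{blockSizes}, \code{blockStarts}). The file is
#' validated before parsing: every non-empty line must have at least 12
#' whitespace-separated columns, and the last block must end at
#' \code{chromEnd}.
#'
#' @param path path to a BED12 file.
#' @param biotype biotype to stamp on all transcripts (\code{"coding"} or
#'   \code{"lncRNA"}).
#' @return a \linkS4class{TranscriptSet}, file order preserved.
#' @seealso \code{\link{writeTranscriptsBed12}}
#' @export
readTranscriptsBed12 <- function(path, biotype = c("coding", "lncRNA")) {
  biotype <- match.arg(biotype)
  if (!file.exists(path))
    stop("no such file: ", path)
  lines <- readLines(path)
  keep <- nzchar(trimws(lines)) &
    !grepl("^(track|browser|#)", lines)
  if (!any(keep))
    return(TranscriptSet(GRangesList(), character(0),
                         biotype = character(0)))
  nfield <- vapply(strsplit(lines[keep], "[ \t]+"), length, integer(1))
  if (any(nfield < 12L))
    stop("malformed BED12 line ", which(keep)[which(nfield < 12L)[1L]],
         ": fewer than 12 columns")
  ## normalise separators so space-delimited files parse identically
  tmp <- tempfile(fileext = ".bed")
  on.exit(unlink(tmp))
  writeLines(gsub("[ \t]+", "\t", trimws(lines[keep])), tmp)
  gr <- rtracklayer::import(tmp, format = "bed")
  if (is.null(gr$blocks))
    stop("file has 12 columns but no block structure was parsed")
  bl <- gr$blocks
  last <- max(end(bl))
  if (any(last != width(gr)))
    stop("block structure inconsistent with chromEnd for transcript(s): ",
         paste(gr$name[last != width(gr)], collapse = ", "))
  n <- length(gr)
  ex <- shift(bl, start(gr) - 1L)
  flat <- unlist(ex, use.names = FALSE)
  exg <- GRanges(rep(seqnames(gr), elementNROWS(ex)),
                 flat,
                 strand = rep(strand(gr), elementNROWS(ex)))
  exl <- relist(exg, ex)
  ids <- as.character(gr$name)
  if (anyDuplicated(ids))
    ids <- make.unique(ids)
  TranscriptSet(exl, txId = ids, biotype = biotype)
}

#' Write transcript models as BED12
#'
#' @param ts a \linkS4class{TranscriptSet}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeTranscriptsBed12 <- function(ts, path) {
  stopifnot(is(ts, "TranscriptSet"))
  grl <- exonRanges(ts)
  names(grl) <- txId(ts)
  rtracklayer::export(grl, path, format = "bed")
  invisible(path)
}

#' Read a probe table
#'
#' The probe table is a two-column tab-separated file: probe identifier and
#' probe sequence. Sequences are uppercased; every probe starts out with
#' status \code{unmapped} and no alignment.
#'
#' @param path path to the probe table.
#' @param params an \linkS4class{ArrayParams}; sequences must have length
#'   \code{probeLength}.
#' @return a \linkS4class{ProbeTable}.
#' @export
readProbeTable <- function(path, params = ArrayParams()) {
  if (!file.exists(path))
    stop("no such file: ", path)
  d <- utils::read.delim(path, header = FALSE, colClasses = "character",
                         col.names = c("probe_id", "sequence"))
  if (ncol(d) != 2L)
    stop("probe table must have exactly two tab-separated columns")
  d$sequence <- toupper(d$sequence)
  bad <- nchar(d$sequence) != params@probeLength
  if (any(bad))
    stop("probe sequence length != ", params@probeLength, " for: ",
         paste(utils::head(d$probe_id[bad], 5L), collapse = ", "))
  if (anyDuplicated(d$probe_id))
    stop("duplicated probe_id: ",
         d$probe_id[anyDuplicated(d$probe_id)])
  if (any(grepl("[^ACGT]", d$sequence)))
    stop("probe sequences must be over the alphabet ACGT")
  ProbeTable(probeId = d$probe_id, sequence = d$sequence)
}

#' Write a probe table
#'
#' @param pt a \linkS4class{ProbeTable}; only \code{probe_id} and
#'   \code{sequence} are written (the on-disk probe-table format carries no
#'   mapping state).
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeProbeTable <- function(pt, path) {
  stopifnot(is(pt, "ProbeTable"))
  utils::write.table(as.data.frame(pt@data[, c("probe_id", "sequence")]),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a probe intensity matrix
#'
#' Tab-separated, first column the feature identifier, header row of sample
#' names, linear-scale intensities.
#'
#' @param path path to the TSV file.
#' @return a numeric matrix (features x samples) with dimnames.
#' @export
readExpressionMatrix <- function(path) {
  if (!file.exists(path))
    stop("no such file: ", path)
  d <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                         colClasses = "character")
  ids <- d[[1L]]
  if (anyDuplicated(ids))
    stop("duplicated feature id: ", ids[anyDuplicated(ids)])
  m <- as.matrix(d[, -1L, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(m), nrow = nrow(m),
                                 dimnames = list(ids, colnames(m))))
  bad <- which(is.na(num) , arr.ind = TRUE)
  if (nrow(bad))
    stop("non-numeric value at feature '", ids[bad[1L, 1L]],
         "', sample '", colnames(num)[bad[1L, 2L]], "'")
  num
}

#' Write an expression matrix
#'
#' Full-precision TSV (feature id column + one column per sample); the
#' exact inverse of \code{\link{readExpressionMatrix}}.
#'
#' @param mat numeric matrix with dimnames.
#' @param path output path.
#' @param idColumn name for the feature-id column.
#' @return \code{path}, invisibly.
#' @export
writeExpressionMatrix <- function(mat, path, idColumn = "feature_id") {
  df <- data.frame(id = rownames(mat),
                   format(mat, digits = 17, trim = TRUE, scientific = TRUE),
                   check.names = FALSE)
  colnames(df) <- c(idColumn, colnames(mat))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a two-group sample design
#'
#' Tab-separated with header \code{sample_id<TAB>group}; exactly two
#' distinct group labels, each with at least two samples.
#'
#' @param path path to the design TSV.
#' @return a named factor (names = sample ids, two levels in order of first
#'   appearance).
#' @export
readGroupDesign <- function(path) {
  d <- utils::read.delim(path, header = TRUE, colClasses = "character")
  if (!all(c("sample_id", "group") %in% colnames(d)))
    stop("design file needs columns sample_id, group")
  groupDesign(d$sample_id, d$group)
}

#' Construct a two-group design
#'
#' @param sampleId character vector of sample names.
#' @param group parallel vector of group labels (exactly two distinct
#'   values, each appearing at least twice).
#' @param ref optional label to use as "group 1"; by default the first
#'   label encountered. Group 1 is the reference sign of all fold changes
#'   and splice indices (group 1 minus group 2).
#' @return a named two-level factor.
#' @export
groupDesign <- function(sampleId, group, ref = NULL) {
  if (anyDuplicated(sampleId))
    stop("duplicated sample_id in design")
  lev <- unique(group)
  if (!is.null(ref)) {
    if (!ref %in% lev)
      stop("ref is not one of the group labels")
    lev <- c(ref, setdiff(lev, ref))
  }
  f <- factor(group, levels = lev)
  if (nlevels(f) != 2L)
    stop("design must have exactly two groups, got ", nlevels(f))
  if (any(table(f) < 2L))
    stop("each group needs at least two samples")
  names(f) <- sampleId
  f
}

#' Write the custom annotation file set
#'
#' Emits the four annotation files: \code{probesets.bed} (BED6, name =
#' probe-set id, score = probe count), \code{clusters.bed} (BED6 per
#' cluster span, score = probe count), \code{meta_probeset.tsv}
#' (cluster id, comma-separated probe-set ids, total probe count) and
#' \code{probe_assignment.tsv} (probe id, probe-set id, chrom, 0-based
#' start, end, strand). Rows are sorted by (chrom, start).
#'
#' @param annotation an \linkS4class{LncAnnotation}.
#' @param outdir output directory (created if needed).
#' @return named character vector of the four file paths, invisibly.
#' @export
writeAnnotationFiles <- function(annotation, outdir) {
  stopifnot(is(annotation, "LncAnnotation"))
  if (!dir.exists(outdir) &&
      !dir.create(outdir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", outdir)
  paths <- c(probesets = file.path(outdir, "probesets.bed"),
             clusters = file.path(outdir, "clusters.bed"),
             meta = file.path(outdir, "meta_probeset.tsv"),
             assignment = file.path(outdir, "probe_assignment.tsv"))

  bedSort <- function(gr) gr[order(as.character(seqnames(gr)), start(gr))]

  ps <- bedSort(annotation@probesets)
  if (length(ps)) {
    psb <- ps
    names(psb) <- ps$probeset_id
    psb$name <- ps$probeset_id
    psb$score <- ps$n_probes
  } else psb <- ps
  rtracklayer::export(psb, paths[["probesets"]], format = "bed")

  cl <- bedSort(annotation@clusters)
  if (length(cl)) {
    clb <- cl
    names(clb) <- cl$cluster_id
    clb$name <- cl$cluster_id
    clb$score <- cl$n_probes
  } else clb <- cl
  rtracklayer::export(clb, paths[["clusters"]], format = "bed")

  meta <- data.frame(
    cluster_id = cl$cluster_id,
    probeset_ids = vapply(cl$cluster_id, function(id)
      paste(ps$probeset_id[ps$cluster_id == id], collapse = ","),
      character(1)),
    n_probes = if (length(cl)) cl$n_probes else integer(0))
  utils::write.table(meta, paths[["meta"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)

  d <- probeData(annotation@probes)
  d <- d[d$status == "assigned", , drop = FALSE]
  d <- d[order(d$chrom, d$start), , drop = FALSE]
  asg <- data.frame(probe_id = d$probe_id, probeset_id = d$probeset_id,
                    chrom = d$chrom, start = d$start - 1L, end = d$end,
                    strand = d$strand)
  utils::write.table(asg, paths[["assignment"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}

#' Read a BED6 file as GRanges
#'
#' Convenience reader for the emitted \code{probesets.bed} /
#' \code{clusters.bed} (name and score kept as metadata).
#'
#' @param path path to a BED file.
#' @return a \code{GRanges}.
#' @export
readBed6 <- function(path) {
  if (!file.exists(path))
    stop("no such file: ", path)
  if (length(readLines(path)) == 0L)
    return(GRanges())
  rtracklayer::import(path, format = "bed")
}

#' Write the positional classification table
#'
#' @param classification data frame from \code{\link{classifyClusters}}.
#' @param path output path (TSV with header).
#' @return \code{path}, invisibly.
#' @export
writeClassification <- function(classification, path) {
  utils::write.table(classification, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
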