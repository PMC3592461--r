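## Accessors and methods for ProbeTable.

#' @rdname ProbeTable
#' @export
setMethod("probeIds", "ProbeTable", function(object) object@data$probe_id)

#' @rdname ProbeTable
#' @export
setMethod("probeStatus", "ProbeTable", function(object) {
  out <- object@data$status
  names(out) <- object@data$probe_id
  out
})

#' @rdname ProbeTable
#' @export
setMethod("probeData", "ProbeTable", function(object) object@data)

#' @rdname ProbeTable
#' @export
setMethod("length", "ProbeTable", function(x) nrow(x@data))

#' @rdname ProbeTable
#' @param i index for subsetting (integer, logical or probe ids).
#' @export
setMethod("[", "ProbeTable", function(x, i) {
  if (is.character(i))
    i <- match(i, x@data$probe_id)
  initialize(x, data = x@data[i, , drop = FALSE])
})

#' @rdname ProbeTable
#' @details \code{probeAlignments} returns the unique genomic placements of
#'   all placed probes (status \code{unassigned}, \code{coding_overlap} or
#'   \code{assigned}) as a \code{GRanges} with \code{probe_id},
#'   \code{status} and \code{probeset_id} metadata.
#' @export
setMethod("probeAlignments", "ProbeTable", function(object) {
  d <- object@data
  placed <- !(d$status %in% c("unmapped", "multimapped"))
  d <- d[placed, , drop = FALSE]
  gr <- GRanges(d$chrom, IRanges(d$start, d$end), strand = d$strand)
  mcols(gr) <- DataFrame(probe_id = d$probe_id, status = d$status,
                         probeset_id = d$probeset_id)
  names(gr) <- d$probe_id
  gr
})

setMethod("show", "ProbeTable", function(object) {
  tab <- table(factor(object@data$status, PROBE_STATUSES))
  cat("ProbeTable:", nrow(object@data), "probe(s)\n")
  for (s in PROBE_STATUSES)
    if (tab[[s]] > 0L) cat("  ", s, ": ", tab[[s]], "\n", sep = "")
})

## internal: replace columns for a subset of probes, keeping validity
updateProbes <- function(pt, idx, ...) {
  d <- pt@data
  repl <- list(...)
  for (col in names(repl))
    d[[col]][idx] <- repl[[col]]
  initialize(pt, data = d)
}
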