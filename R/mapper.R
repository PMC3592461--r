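## Exact-match probe mapping. A zero-mismatch short-read aligner
## degenerates to exact string matching, so probes are placed with a k-mer
## hash of the genome: every forward-strand window of length k is indexed;
## querying a probe sequence gives its forward-strand hits and querying its
## reverse complement gives the reverse-strand hits. Probes hitting no
## locus or more than one locus (counting both strands) are discarded.

#' Build an exact-match k-mer index of a genome
#'
#' Indexes every forward-strand window of length \code{probeLength}.
#' Windows containing any character outside ACGT (e.g. N) are skipped:
#' N never matches any base.
#'
#' @param genome a \code{DNAStringSet}, a named character vector of
#'   sequences, or the path to a FASTA file.
#' @param params an \linkS4class{ArrayParams}; \code{probeLength} is the
#'   word length k.
#' @return a \linkS4class{KmerIndex}.
#' @examples
#' idx <- buildKmerIndex(c(chr1 = "ACGTACGT"), ArrayParams(probeLength = 4))
#' idx
#' @export
buildKmerIndex <- function(genome, params = ArrayParams()) {
  k <- params@probeLength
  seqs <- asGenomeStrings(genome)
  if (length(seqs) == 0L || sum(nchar(seqs)) == 0L)
    stop("empty genome")
  chromV <- character(0)
  startV <- integer(0)
  wordV <- character(0)
  for (chr in names(seqs)) {
    s <- seqs[[chr]]
    L <- nchar(s)
    if (L < k) next
    starts <- seq_len(L - k + 1L)
    words <- substring(s, starts, starts + k - 1L)
    ok <- !grepl("[^ACGT]", words)
    if (!any(ok)) next
    chromV <- c(chromV, rep(chr, sum(ok)))
    startV <- c(startV, starts[ok])
    wordV <- c(wordV, words[ok])
  }
  if (length(wordV)) {
    fac <- factor(wordV)
    buckets <- unname(split(seq_along(wordV), fac))
    words <- levels(fac)
  } else {
    buckets <- list()
    words <- character(0)
  }
  new("KmerIndex", k = k, words = words, buckets = buckets,
      chrom = chromV, start = startV,
      seqLengths = stats::setNames(nchar(seqs), names(seqs)))
}

## internal: coerce FASTA path / DNAStringSet / character to named strings
asGenomeStrings <- function(genome) {
  if (is.character(genome) && length(genome) == 1L && file.exists(genome))
    genome <- Biostrings::readDNAStringSet(genome)
  if (is(genome, "DNAStringSet")) {
    out <- as.character(genome)
    names(out) <- sub("\\s.*$", "", names(genome))
    return(toupper(out))
  }
  if (is.character(genome)) {
    if (length(genome) == 0L)
      return(stats::setNames(character(0), character(0)))
    if (is.null(names(genome)))
      stop("genome sequences must be named")
    return(toupper(genome))
  }
  stop("cannot interpret genome of class ", class(genome)[1L])
}

#' Number of placements of each query word
#'
#' Looks up a character vector of k-mers in the index and returns, for each,
#' the forward-strand placements (the reverse complement must be queried
#' separately for reverse-strand hits).
#'
#' @param index a \linkS4class{KmerIndex}.
#' @param words character vector of k-mers.
#' @return a list parallel to \code{words}; each element an integer vector
#'   of placement indices (into the index's placement table), empty when
#'   the word does not occur.
#' @keywords internal
lookupWords <- function(index, words) {
  j <- match(words, index@words)
  out <- vector("list", length(words))
  hit <- !is.na(j)
  out[hit] <- index@buckets[j[hit]]
  out[!hit] <- list(integer(0))
  out
}

#' Map probes to the genome by exact unique matching
#'
#' Each probe is looked up on both strands: forward hits from the probe
#' sequence, reverse hits from its reverse complement. A probe with exactly
#' one placement in total gets that alignment and status \code{unassigned};
#' zero placements gives \code{unmapped}; two or more (including a
#' reverse-complement-palindromic probe matching a single locus on both
#' strands) gives \code{multimapped} with no alignment. Input order is
#' preserved and the result is independent of it.
#'
#' @param probes a \linkS4class{ProbeTable} with status \code{unmapped}.
#' @param index a \linkS4class{KmerIndex} with \code{k} equal to the probe
#'   length.
#' @return the updated \linkS4class{ProbeTable}.
#' @export
mapProbes <- function(probes, index) {
  stopifnot(is(probes, "ProbeTable"), is(index, "KmerIndex"))
  d <- probeData(probes)
  if (!all(d$status == "unmapped"))
    stop("mapProbes expects all probes with status 'unmapped'")
  if (nrow(d) == 0L)
    return(probes)
  if (any(nchar(d$sequence) != index@k))
    stop("probe length does not match index word length k = ", index@k)
  fwd <- lookupWords(index, d$sequence)
  rcseq <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(d$sequence)))
  rev <- lookupWords(index, rcseq)
  nf <- lengths(fwd)
  nr <- lengths(rev)
  total <- nf + nr
  status <- rep("unmapped", nrow(d))
  status[total >= 2L] <- "multimapped"
  uniq <- which(total == 1L)
  status[uniq] <- "unassigned"
  chrom <- rep(NA_character_, nrow(d))
  start <- rep(NA_integer_, nrow(d))
  strandv <- rep(NA_character_, nrow(d))
  for (i in uniq) {
    if (nf[i] == 1L) {
      p <- fwd[[i]][1L]
      strandv[i] <- "+"
    } else {
      p <- rev[[i]][1L]
      strandv[i] <- "-"
    }
    chrom[i] <- index@chrom[p]
    start[i] <- index@start[p]
  }
  dd <- probes@data
  dd$status <- status
  dd$chrom <- chrom
  dd$start <- start
  dd$end <- ifelse(is.na(start), NA_integer_, start + index@k - 1L)
  dd$strand <- strandv
  initialize(probes, data = dd)
}
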