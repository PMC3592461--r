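## Independent oracles used across the suite. Each is a deliberately
## naive implementation (brute force, base-by-base, textbook formula)
## kept free of the code paths it checks.

`%||%` <- function(a, b) if (is.null(a)) b else a

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
  library(S4Vectors)
})

## Brute-force probe mapping: scan every chromosome string on both
## strands with fixed-pattern matching. Returns a data.frame with one row
## per probe: status, chrom, start, strand (NA unless uniquely placed).
oracleScanMap <- function(seqs, probeSeqs) {
  rcStr <- function(s) chartr("ACGT", "TGCA",
                              paste(rev(strsplit(s, "")[[1]]),
                                    collapse = ""))
  out <- data.frame(status = character(length(probeSeqs)),
                    chrom = NA_character_, start = NA_integer_,
                    strand = NA_character_)
  for (i in seq_along(probeSeqs)) {
    p <- probeSeqs[i]
    rc <- rcStr(p)
    hits <- list()
    for (chr in names(seqs)) {
      for (str in c("+", "-")) {
        pat <- if (str == "+") p else rc
        m <- gregexpr(pat, seqs[[chr]], fixed = TRUE)[[1]]
        ## gregexpr skips overlapping occurrences; rescan from each hit+1
        pos <- integer(0)
        from <- 1L
        while (TRUE) {
          j <- regexpr(pat, substring(seqs[[chr]], from), fixed = TRUE)
          if (j < 0) break
          pos <- c(pos, from + j - 1L)
          from <- from + j
        }
        for (s0 in pos)
          hits[[length(hits) + 1L]] <- list(chr, s0, str)
      }
    }
    if (length(hits) == 0L) {
      out$status[i] <- "unmapped"
    } else if (length(hits) > 1L) {
      out$status[i] <- "multimapped"
    } else {
      out$status[i] <- "unassigned"
      out$chrom[i] <- hits[[1]][[1]]
      out$start[i] <- hits[[1]][[2]]
      out$strand[i] <- hits[[1]][[3]]
    }
  }
  out
}

## Base-by-base segmentation oracle: label every covered position with
## the sorted set of transcripts whose exons cover it; probe sets are the
## maximal runs of constant non-empty label. `exons` is a data.frame with
## columns tx, start, end (1-based inclusive).
oracleSegments <- function(exons) {
  lo <- min(exons$start)
  hi <- max(exons$end)
  ## per-position label: concatenation of the ids of all covering
  ## transcripts (exon rows visited in fixed order; exons of one
  ## transcript are disjoint, so the label is its covering set)
  lab <- character(hi - lo + 1L)
  for (r in order(exons$tx)) {
    idx <- (exons$start[r] - lo + 1L):(exons$end[r] - lo + 1L)
    lab[idx] <- paste(lab[idx], exons$tx[r], sep = ",")
  }
  covered <- nzchar(lab)
  ## maximal runs of constant non-empty label
  newRun <- covered & (c(TRUE, lab[-1L] != lab[-length(lab)]) |
                         !c(FALSE, covered[-length(covered)]))
  runId <- cumsum(newRun)
  runId[!covered] <- NA_integer_
  pos <- lo:hi
  starts <- tapply(pos[covered], runId[covered], min)
  ends <- tapply(pos[covered], runId[covered], max)
  IRanges(as.integer(starts), as.integer(ends))
}

## O(n^2) connected components over same-strand exon overlap; `txList` is
## a list of GRanges (one per transcript). Returns an integer component
## label per transcript (canonicalised to first-occurrence order).
oracleComponents <- function(txList) {
  n <- length(txList)
  chrom <- vapply(txList, function(g) as.character(seqnames(g)[1]),
                  character(1))
  str <- vapply(txList, function(g) as.character(strand(g)[1]),
                character(1))
  st <- lapply(txList, start)
  en <- lapply(txList, end)
  ## explicit O(n^2) pairwise adjacency: same chrom, same strand, any
  ## exon pair sharing >= 1 bp
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i) next
      if (chrom[i] != chrom[j] || str[i] != str[j]) next
      hit <- any(outer(st[[i]], en[[j]], "<=") &
                   outer(en[[i]], st[[j]], ">="))
      adj[i, j] <- adj[j, i] <- hit
    }
  }
  comp <- rep(NA_integer_, n)
  nxt <- 0L
  for (i in seq_len(n)) {
    if (!is.na(comp[i])) next
    nxt <- nxt + 1L
    queue <- i
    comp[i] <- nxt
    while (length(queue)) {
      u <- queue[1L]; queue <- queue[-1L]
      reach <- which(adj[u, ] & is.na(comp))
      comp[reach] <- nxt
      queue <- c(queue, reach)
    }
  }
  comp
}

## Textbook Tukey median polish (row sweep, overall from column effects,
## column sweep, overall from row effects; stop when the total absolute
## residual stops changing).
oracleMedpolish <- function(x, eps = 1e-6, maxiter = 10L) {
  t0 <- 0
  r <- rep(0, nrow(x)); cc <- rep(0, ncol(x))
  z <- x
  oldsum <- 0
  for (it in seq_len(maxiter)) {
    rdelta <- apply(z, 1L, stats::median)
    z <- z - rdelta
    r <- r + rdelta
    delta <- stats::median(cc)
    cc <- cc - delta
    t0 <- t0 + delta
    cdelta <- apply(z, 2L, stats::median)
    z <- sweep(z, 2L, cdelta)
    cc <- cc + cdelta
    delta <- stats::median(r)
    r <- r - delta
    t0 <- t0 + delta
    newsum <- sum(abs(z))
    if (newsum == 0 || abs(newsum - oldsum) < eps * newsum) break
    oldsum <- newsum
  }
  list(overall = t0, row = r, col = cc, residuals = z)
}

## Textbook Welch two-sample t-test p-value.
oracleWelchP <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  v1 <- stats::var(x); v2 <- stats::var(y)
  se2 <- v1 / n1 + v2 / n2
  t <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  2 * stats::pt(-abs(t), df)
}

## Random transcript structures on a small coordinate range, for the
## segmentation / clustering property tests: one row per exon, columns
## tx / chrom / strand / start / end.
randomTxTable <- function(n, chroms = c("chrA", "chrB"),
                          maxStart = 4000L, maxExons = 8L,
                          strands = c("+", "-")) {
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    ne <- sample.int(maxExons, 1L)
    w <- sample(20:120, ne, replace = TRUE)
    gap <- sample(10:150, ne, replace = TRUE)
    starts <- sample.int(maxStart, 1L) + cumsum(c(0L, (w + gap)[-ne]))
    rows[[i]] <- data.frame(
      tx = i,
      chrom = if (length(chroms) > 1L) sample(chroms, 1L) else chroms,
      strand = if (length(strands) > 1L) sample(strands, 1L) else strands,
      start = starts, end = starts + w - 1L)
  }
  do.call(rbind, rows)
}

## Table -> list of per-transcript exon GRanges (for the oracles).
tableToTxList <- function(df)
  lapply(split(df, df$tx), function(d)
    GRanges(d$chrom[1L], IRanges(d$start, d$end), strand = d$strand[1L]))

## Table -> TranscriptSet of lncRNAs, built through a single flat GRanges
## (cheap relist instead of a GRangesList() over many small objects).
tableToLncSet <- function(df, ids = NULL) {
  txFac <- factor(df$tx, unique(df$tx))
  if (is.null(ids)) ids <- sprintf("T%03d", as.integer(levels(txFac)))
  flat <- GRanges(df$chrom, IRanges(df$start, df$end), strand = df$strand)
  grl <- relist(flat[order(as.integer(txFac))],
                PartitioningByEnd(cumsum(as.integer(table(txFac)))))
  TranscriptSet(grl, txId = ids, biotype = "lncRNA")
}

randomTxList <- function(n, chroms = c("chrA", "chrB"),
                         maxStart = 4000L, maxExons = 8L) {
  unname(tableToTxList(randomTxTable(n, chroms, maxStart, maxExons)))
}

## Wrap a list of exon GRanges into a TranscriptSet of lncRNAs.
asLncSet <- function(txList, ids = sprintf("T%03d", seq_along(txList))) {
  TranscriptSet(GRangesList(txList), txId = ids, biotype = "lncRNA")
}

## A ProbeTable of already-placed probes (status unassigned), for filter
## and assignment tests that need no mapping step.
placedProbes <- function(ids, chrom, start, end, strand) {
  ProbeTable(probeId = ids,
             sequence = vapply(end - start + 1L, function(w)
               paste(rep("A", w), collapse = ""), character(1)),
             chrom = chrom, start = start, end = end, strand = strand,
             status = "unassigned")
}

## Deterministic tiny two-cluster annotation plus a simulated-intensity
## design, shared by expression tests.
tinyAnnotation <- function() {
  txl <- list(
    GRanges("chr1", IRanges(c(101, 301), c(200, 400)), strand = "+"),
    GRanges("chr1", IRanges(c(151, 301), c(250, 400)), strand = "+"),
    GRanges("chr1", IRanges(1001, 1300), strand = "-"))
  ts <- asLncSet(txl, c("L1", "L2", "L3"))
  cs <- clusterTranscripts(ts)
  segs <- segmentProbesets(cs)
  ## probes fully inside segments on the matching strand
  mk <- function(gr) {
    n <- length(gr)
    placedProbes(sprintf("pr%02d", seq_len(n)),
                 as.character(seqnames(gr)), start(gr), end(gr),
                 as.character(strand(gr)))
  }
  probes <- GRanges()
  for (i in seq_along(segs)) {
    w <- width(segs)[i]
    offs <- seq(1L, w - 24L, by = 30L)
    probes <- c(probes, GRanges(seqnames(segs)[i],
                                IRanges(start(segs)[i] + offs - 1L,
                                        width = 25L),
                                strand = strand(segs)[i]))
  }
  pt <- mk(probes)
  assignProbes(pt, cs, segs)
}
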