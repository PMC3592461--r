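## Seeded generators for toy genomes, transcriptomes, probe tables and
## intensity matrices with known ground truth. Every generator is a pure
## function of its seed and parameters; the global RNG state is restored
## on exit.

## internal: evaluate expr under a fixed seed without disturbing the
## caller's RNG stream
withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate a toy genome
#'
#' Uniform random ACGT sequences, deterministic per seed. To provide known
#' multi-mapping probes, \code{nRepeats} windows of \code{repeatWidth} bp
#' are copied from one locus to another inside a reserved repeat zone (the
#' last 5 percent of each chromosome, which \code{\link{makeTranscriptome}}
#' avoids); the duplicated loci are recorded in
#' \code{metadata(genome)$repeats}.
#'
#' @param seed integer seed.
#' @param nChroms number of chromosomes (named chr1, chr2, ...).
#' @param length chromosome length in bp (>= 1000).
#' @param nRepeats number of planted duplicated windows.
#' @param repeatWidth width of each duplicated window (probe length).
#' @return a \code{DNAStringSet}.
#' @export
makeToyGenome <- function(seed, nChroms = 2L, length = 150000L,
                          nRepeats = 3L, repeatWidth = 25L) {
  stopifnot(length >= 1000L, nChroms >= 1L)
  withSeed(seed, {
    seqs <- vapply(seq_len(nChroms), function(i)
      paste(sample(c("A", "C", "G", "T"), length, replace = TRUE),
            collapse = ""), character(1))
    names(seqs) <- paste0("chr", seq_len(nChroms))
    rep_df <- NULL
    geneZone <- as.integer(length * 0.95)
    if (nRepeats > 0L) {
      ## repeat zone at the chromosome tail, after the gene zone
      blk <- nRepeats * (repeatWidth + 75L)
      src_base <- length - 2L * blk - 100L
      dst_base <- length - blk - 50L
      stopifnot(src_base > 0L)
      geneZone <- min(geneZone, src_base - 100L)
      src_chr <- rep_len("chr1", nRepeats)
      src_start <- src_base + (seq_len(nRepeats) - 1L) * (repeatWidth + 75L)
      dst_chr <- rep_len(names(seqs)[nChroms], nRepeats)
      dst_start <- dst_base + (seq_len(nRepeats) - 1L) * (repeatWidth + 75L)
      stopifnot(max(dst_start) + repeatWidth - 1L <= length)
      for (i in seq_len(nRepeats)) {
        word <- substring(seqs[[src_chr[i]]], src_start[i],
                          src_start[i] + repeatWidth - 1L)
        substring(seqs[[dst_chr[i]]], dst_start[i],
                  dst_start[i] + repeatWidth - 1L) <- word
      }
      rep_df <- data.frame(src_chrom = src_chr, src_start = src_start,
                           dst_chrom = dst_chr, dst_start = dst_start,
                           width = repeatWidth)
    }
    g <- Biostrings::DNAStringSet(seqs)
    S4Vectors::metadata(g) <- list(repeats = rep_df,
                                   gene_zone_end = geneZone)
    g
  })
}

## internal: one multi-exon structure starting at `base`, exon widths and
## intron widths drawn from the given ranges
drawExons <- function(base, nExons, exonRange, intronRange) {
  w <- as.integer(round(stats::runif(nExons, exonRange[1], exonRange[2])))
  g <- if (nExons > 1L)
    as.integer(round(stats::runif(nExons - 1L, intronRange[1],
                                  intronRange[2])))
  else integer(0)
  starts <- base + cumsum(c(0L, utils::head(w, -1L) + g))
  IRanges(starts, width = w)
}

#' Generate a toy transcriptome with known positional structure
#'
#' Places protein-coding genes in regularly spaced slots and lncRNAs around
#' them so that every positional category occurs: sense (partially
#' overlapping coding exons on the same strand, probes on the free exon
#' survive), a fully exon-contained sense lncRNA whose probes are all
#' removed by the coding filter (its cluster is later deleted by the
#' empty-probe-set rule), antisense, intronic, bidirectional (head-to-head
#' across a short gap), extension (downstream, same strand), close
#' (proximate, opposite strand, not head-to-head) and intergenic. A
#' fraction of lncRNAs is drawn as same-strand overlapping partners of
#' already placed multi-exon lncRNAs (yielding clusters whose segmentation
#' has three or more probe sets), and \code{nShort} single-exon lncRNAs of
#' 200 nt or shorter exercise the length filter. At least 60 percent of
#' lncRNAs are multi-exon.
#'
#' @param seed integer seed.
#' @param genome a genome from \code{\link{makeToyGenome}}.
#' @param nCoding number of protein-coding genes.
#' @param nLncrna number of lncRNAs (excluding the short decoys).
#' @param overlapFraction fraction of lncRNAs involved in same-strand
#'   overlaps; \code{floor(overlapFraction * nLncrna / 2)} lncRNAs are
#'   generated as partners overlapping a seed transcript.
#' @param nShort number of planted short (<= 200 nt) lncRNAs.
#' @return a \linkS4class{TranscriptSet} with both biotypes.
#' @export
makeTranscriptome <- function(seed, genome, nCoding = 10L, nLncrna = 24L,
                              overlapFraction = 0.5, nShort = 2L) {
  stopifnot(nCoding >= 7L, nLncrna >= 7L)
  seqs <- asGenomeStrings(genome)
  zoneEnd <- S4Vectors::metadata(genome)$gene_zone_end
  if (is.null(zoneEnd))
    zoneEnd <- as.integer(min(nchar(seqs)) * 0.95)
  nChroms <- length(seqs)
  slotWidth <- 12000L
  perChrom <- ceiling(nCoding / nChroms)
  withSeed(seed, {
    ## ---- coding genes ----
    exl <- list(); ids <- character(0); bts <- character(0)
    chrV <- character(0); strV <- character(0)
    codingInfo <- vector("list", nCoding)
    for (g in seq_len(nCoding)) {
      chr <- names(seqs)[((g - 1L) %/% perChrom) + 1L]
      slot <- ((g - 1L) %% perChrom)
      base <- 2500L + slot * slotWidth
      strand <- if (g %% 2L == 1L) "+" else "-"
      ne <- sample(3:5, 1L)
      ir <- drawExons(base, ne, c(120, 250), c(400, 800))
      if (max(end(ir)) > zoneEnd)
        stop("coding gene placement exceeds the usable genome; ",
             "increase the genome length")
      id <- sprintf("PC%03d", g)
      exl[[length(exl) + 1L]] <- GRanges(chr, ir, strand = strand)
      ids <- c(ids, id); bts <- c(bts, "coding")
      codingInfo[[g]] <- list(id = id, chr = chr, strand = strand, ir = ir)
    }
    geneZoneEnd <- 2500L + perChrom * slotWidth

    addLnc <- function(chr, ir, strand, tag) {
      id <- sprintf("LNC%03d", sum(bts == "lncRNA") + 1L)
      exl[[length(exl) + 1L]] <<- GRanges(chr, ir, strand = strand)
      ids <<- c(ids, id); bts <<- c(bts, "lncRNA")
      id
    }
    flip <- function(s) if (s == "+") "-" else "+"

    ## ---- category-anchored lncRNAs ----
    plan <- c("sense", "sense_dropped", "antisense", "intronic",
              "bidirectional", "extension", "close")
    nIntergenic <- nLncrna - length(plan)
    multiexonSeeds <- integer(0)   # indices (within lncRNAs) usable as seeds
    for (j in seq_along(plan)) {
      G <- codingInfo[[j]]
      ir <- G$ir
      cat_ <- plan[j]
      if (cat_ == "sense") {
        ## first exon overlaps coding exon 2, second exon sits in intron 2
        e1 <- IRanges(start(ir)[2L] + 30L, end(ir)[2L] + 60L)
        e2 <- IRanges(end(ir)[2L] + 140L,
                      width = min(180L, start(ir)[3L] - end(ir)[2L] - 180L))
        addLnc(G$chr, c(e1, e2), G$strand)
      } else if (cat_ == "sense_dropped") {
        ## both exons fully inside coding exons: every probe overlaps the
        ## coding mask, so the resulting cluster loses all probe sets
        e1 <- IRanges(start(ir)[1L] + 5L, width = width(ir)[1L] - 15L)
        e2 <- IRanges(start(ir)[2L] + 5L, width = width(ir)[2L] - 15L)
        addLnc(G$chr, c(e1, e2), G$strand)
      } else if (cat_ == "antisense") {
        e1 <- IRanges(start(ir)[2L] + 20L, end(ir)[2L] + 80L)
        e2 <- IRanges(end(ir)[2L] + 160L, width = 140L)
        addLnc(G$chr, c(e1, e2), flip(G$strand))
      } else if (cat_ == "intronic") {
        ## inside intron 2 (between exons 2 and 3), margins >= 20 bp
        intr <- IRanges(end(ir)[2L] + 1L, start(ir)[3L] - 1L)
        e1 <- IRanges(start(intr) + 25L, width = 110L)
        e2 <- IRanges(end(e1) + 40L, width = 120L)
        addLnc(G$chr, c(e1, e2), G$strand)
      } else if (cat_ == "bidirectional") {
        gap <- sample(120:450, 1L)
        if (G$strand == "+") {
          e2 <- IRanges(min(start(ir)) - gap - 130L, width = 130L)
          e1 <- IRanges(start(e2) - 300L, width = 140L)
          addLnc(G$chr, c(e1, e2), "-")
        } else {
          e1 <- IRanges(max(end(ir)) + gap + 1L, width = 130L)
          e2 <- IRanges(end(e1) + 170L, width = 140L)
          addLnc(G$chr, c(e1, e2), "+")
        }
      } else if (cat_ == "extension") {
        gap <- sample(100:600, 1L)
        if (G$strand == "+") {
          e1 <- IRanges(max(end(ir)) + gap + 1L, width = 150L)
          e2 <- IRanges(end(e1) + 200L, width = 120L)
        } else {
          e2 <- IRanges(min(start(ir)) - gap - 150L, width = 150L)
          e1 <- IRanges(start(e2) - 320L, width = 120L)
        }
        addLnc(G$chr, c(e1, e2), G$strand)
      } else if (cat_ == "close") {
        gap <- sample(100:600, 1L)
        if (G$strand == "+") {
          e1 <- IRanges(max(end(ir)) + gap + 1L, width = 150L)
          e2 <- IRanges(end(e1) + 180L, width = 130L)
          addLnc(G$chr, c(e1, e2), "-")
        } else {
          e2 <- IRanges(min(start(ir)) - gap - 150L, width = 150L)
          e1 <- IRanges(start(e2) - 300L, width = 130L)
          addLnc(G$chr, c(e1, e2), "+")
        }
      }
    }

    ## ---- intergenic lncRNAs (also the pool of overlap seeds) ----
    nPartners <- min(floor(overlapFraction * nLncrna / 2),
                     max(nIntergenic - 1L, 0L))
    nSeeds <- nIntergenic - nPartners
    seedInfo <- vector("list", nSeeds)
    cursor <- geneZoneEnd + 800L
    chrTail <- names(seqs)[length(seqs)]
    for (j in seq_len(nSeeds)) {
      chr <- names(seqs)[((j - 1L) %% nChroms) + 1L]
      strand <- if (j %% 2L == 0L) "-" else "+"
      ne <- sample(2:3, 1L)
      ir <- drawExons(cursor, ne, c(110, 220), c(120, 400))
      if (max(end(ir)) > zoneEnd - 200L)
        stop("intergenic placement exceeds the usable genome")
      addLnc(chr, ir, strand)
      seedInfo[[j]] <- list(chr = chr, strand = strand, ir = ir)
      cursor <- max(end(ir)) + 2600L
    }
    ## partners: same strand, exons derived from a seed so that at least
    ## one exon boundary falls inside a seed exon (>= 3 probe sets)
    for (p in seq_len(nPartners)) {
      s <- seedInfo[[((p - 1L) %% nSeeds) + 1L]]
      ir <- s$ir
      e1 <- IRanges(start(ir)[1L] + 30L, end(ir)[1L] + 45L)
      eL <- IRanges(start(ir)[length(ir)] - 45L, end(ir)[length(ir)])
      addLnc(s$chr, c(e1, eL), s$strand)
    }
    ## ---- short decoys (<= 200 nt spliced) ----
    for (j in seq_len(nShort)) {
      ir <- IRanges(cursor, width = 120L + 20L * j)
      if (max(end(ir)) > zoneEnd - 200L)
        stop("short-decoy placement exceeds the usable genome")
      addLnc(chrTail, ir, "+")
      cursor <- max(end(ir)) + 1500L
    }
    TranscriptSet(GRangesList(exl), txId = ids, biotype = bts)
  })
}

#' Generate a probe table tiled over a transcriptome
#'
#' 25-mers (the configured probe length) are copied from the genome at
#' regular offsets within every exon, on the sense strand of the
#' transcript, and deduplicated by genomic window. Known multi-mapping
#' probes are planted from the genome's duplicated repeat windows, and
#' known unmapped probes are random sequences verified absent from both
#' strands of the genome.
#'
#' @param seed integer seed.
#' @param genome a genome from \code{\link{makeToyGenome}}.
#' @param transcripts a \linkS4class{TranscriptSet} to tile.
#' @param spacing probe start-to-start spacing in bp within an exon.
#' @param nUnmapped number of planted non-genomic probes.
#' @param params an \linkS4class{ArrayParams}.
#' @return a list with elements \code{probes} (a \linkS4class{ProbeTable},
#'   all status \code{unmapped}) and \code{truth} (data frame with the
#'   planted class of every probe: \code{tiled}, \code{multimapped} or
#'   \code{unmapped}, plus the intended placement for tiled probes).
#' @export
makeProbeTable <- function(seed, genome, transcripts, spacing = 35L,
                           nUnmapped = 5L, params = ArrayParams()) {
  k <- params@probeLength
  seqs <- asGenomeStrings(genome)
  withSeed(seed, {
    exl <- exonRanges(transcripts)
    flat <- unlist(exl, use.names = FALSE)
    winChr <- character(0); winStart <- integer(0); winStrand <- character(0)
    for (i in seq_along(flat)) {
      w <- width(flat)[i]
      if (w < k) next                       # exon shorter than a probe
      offs <- seq(1L, w - k + 1L, by = spacing)
      winChr <- c(winChr, rep(as.character(seqnames(flat)[i]), length(offs)))
      winStart <- c(winStart, start(flat)[i] + offs - 1L)
      winStrand <- c(winStrand, rep(as.character(strand(flat)[i]),
                                    length(offs)))
    }
    dup <- duplicated(paste(winChr, winStart, winStrand))
    winChr <- winChr[!dup]; winStart <- winStart[!dup]
    winStrand <- winStrand[!dup]
    seqFwd <- substring(seqs[winChr], winStart, winStart + k - 1L)
    isRev <- winStrand == "-"
    seqProbe <- seqFwd
    if (any(isRev))
      seqProbe[isRev] <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(seqFwd[isRev])))
    truth <- data.frame(planted = rep("tiled", length(seqProbe)),
                        chrom = winChr, start = winStart,
                        strand = winStrand)
    ## planted multi-mappers from the genome's duplicated windows
    reps <- S4Vectors::metadata(genome)$repeats
    if (!is.null(reps) && nrow(reps)) {
      mseq <- substring(seqs[reps$src_chrom], reps$src_start,
                        reps$src_start + k - 1L)
      seqProbe <- c(seqProbe, mseq)
      truth <- rbind(truth, data.frame(
        planted = "multimapped", chrom = NA_character_,
        start = NA_integer_, strand = NA_character_)[rep(1L, nrow(reps)), ])
    }
    ## planted unmapped probes: random k-mers absent from both strands
    absent <- character(0)
    tries <- 0L
    while (length(absent) < nUnmapped && tries < 200L) {
      tries <- tries + 1L
      cand <- paste(sample(c("A", "C", "G", "T"), k, replace = TRUE),
                    collapse = "")
      rc <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(cand)))
      hit <- any(vapply(seqs, function(s)
        grepl(cand, s, fixed = TRUE) || grepl(rc, s, fixed = TRUE),
        logical(1)))
      if (!hit) absent <- c(absent, cand)
    }
    if (length(absent) < nUnmapped)
      stop("could not generate enough non-genomic probe sequences")
    seqProbe <- c(seqProbe, absent)
    truth <- rbind(truth, data.frame(
      planted = "unmapped", chrom = NA_character_, start = NA_integer_,
      strand = NA_character_)[rep(1L, nUnmapped), ])
    ids <- sprintf("P%06d", seq_along(seqProbe))
    truth <- cbind(probe_id = ids, truth)
    rownames(truth) <- NULL
    list(probes = ProbeTable(probeId = ids, sequence = seqProbe),
         truth = truth)
  })
}

#' Simulate probe intensities with a log-additive model
#'
#' The log2 intensity of probe i in sample s is
#' mu + a_i + b_c(i) + de(c(i), s) + sp(ps(i), s) + eps, with probe
#' affinities a ~ Normal(0, tau^2), cluster baselines b ~ Normal(0,
#' clusterSd^2), planted cluster-level (de) and probe-set-level (sp) group
#' effects added to the stated group's samples, and measurement noise
#' eps ~ Normal(0, sigma^2). The returned matrix is linear (2^log2).
#'
#' @param seed integer seed.
#' @param annotation an \linkS4class{LncAnnotation} (probes assigned).
#' @param design named factor from \code{\link{groupDesign}}.
#' @param spliceEffects optional data frame with columns
#'   \code{probeset_id}, \code{delta} (log2), \code{group}.
#' @param deEffects optional data frame with columns \code{cluster_id},
#'   \code{delta} (log2), \code{group}.
#' @param mu baseline log2 intensity.
#' @param tau probe-affinity standard deviation (log2 units).
#' @param sigma noise standard deviation (log2 units).
#' @param clusterSd cluster-baseline standard deviation (log2 units).
#' @return linear intensity matrix, rows = assigned probes, columns =
#'   samples of the design.
#' @export
simulateIntensities <- function(seed, annotation, design,
                                spliceEffects = NULL, deEffects = NULL,
                                mu = 8, tau = 0.5, sigma = 0.25,
                                clusterSd = 1) {
  stopifnot(is(annotation, "LncAnnotation"))
  d <- probeData(probeTable(annotation))
  d <- d[d$status == "assigned", , drop = FALSE]
  if (nrow(d) == 0L)
    stop("annotation has no assigned probes")
  psOf <- d$probeset_id
  clOf <- unname(probesetToCluster(annotation)[psOf])
  samples <- names(design)
  grp <- as.character(design)
  withSeed(seed, {
    a <- stats::rnorm(nrow(d), 0, tau)
    clusters <- unique(clOf)
    b <- stats::setNames(stats::rnorm(length(clusters), 0, clusterSd),
                         clusters)
    l2 <- matrix(mu + a + b[clOf], nrow(d), length(samples),
                 dimnames = list(d$probe_id, samples))
    if (!is.null(deEffects) && nrow(deEffects)) {
      for (r in seq_len(nrow(deEffects))) {
        hit <- clOf == deEffects$cluster_id[r]
        inG <- grp == as.character(deEffects$group[r])
        l2[hit, inG] <- l2[hit, inG] + deEffects$delta[r]
      }
    }
    if (!is.null(spliceEffects) && nrow(spliceEffects)) {
      for (r in seq_len(nrow(spliceEffects))) {
        hit <- psOf == spliceEffects$probeset_id[r]
        inG <- grp == as.character(spliceEffects$group[r])
        l2[hit, inG] <- l2[hit, inG] + spliceEffects$delta[r]
      }
    }
    l2 <- l2 + matrix(stats::rnorm(length(l2), 0, sigma), nrow(l2))
    2^l2
  })
}
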