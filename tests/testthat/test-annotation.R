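mkTx <- function(starts, ends, strand = "+", chrom = "chr1",
                 id = "T1", biotype = "lncRNA")
  TranscriptSet(GRangesList(GRanges(chrom, IRanges(starts, ends),
                                    strand = strand)),
                txId = id, biotype = biotype)

test_that("lncRNAs of 200 nt or shorter are discarded, longer kept", {
  ## spliced lengths 200 (dropped), 201 (kept), and a 250-nt two-exon
  ## transcript spanning 1000 bp (kept: spliced, not genomic, length)
  ts <- c(mkTx(1001, 1200, id = "len200"),
          mkTx(2001, 2201, id = "len201"),
          mkTx(c(5001, 5851), c(5150, 5950), id = "spliced250"))
  kept <- filterShortLncrnas(ts)
  expect_equal(txId(kept), c("len201", "spliced250"))
  expect_equal(length(filterShortLncrnas(asLncSet(list()))), 0L)
  expect_error(filterShortLncrnas(mkTx(1, 300, biotype = "coding")),
               "lncRNA")
})

test_that("coding-exon mask merges overlapping exons per strand", {
  a <- mkTx(101, 200, id = "A", biotype = "coding")
  b <- mkTx(151, 250, id = "B", biotype = "coding")
  m <- codingExonMask(a, b)
  expect_equal(length(m), 1L)
  expect_equal(start(m), 101L)
  expect_equal(end(m), 250L)

  c2 <- mkTx(101, 200, strand = "-", id = "C", biotype = "coding")
  m2 <- codingExonMask(a, c2)
  expect_equal(length(m2), 2L)
  expect_setequal(as.character(strand(m2)), c("+", "-"))
  expect_error(codingExonMask(mkTx(1, 300, id = "L")), "coding")
})

test_that("mask of several sources equals mask of their concatenation", {
  withr::local_seed(31)
  for (rep in 1:5) {
    srcs <- lapply(1:3, function(s)
      TranscriptSet(GRangesList(randomTxList(6)),
                    txId = sprintf("S%d_%d", s, 1:6), biotype = "coding"))
    m1 <- codingExonMask(srcs[[1]], srcs[[2]], srcs[[3]])
    m2 <- codingExonMask(do.call(c, srcs))
    ## base-by-base coverage comparison
    cov1 <- unlist(GenomicRanges::coverage(m1))
    cov2 <- unlist(GenomicRanges::coverage(m2))
    expect_identical(as.logical(cov1 > 0), as.logical(cov2 > 0))
    expect_true(isDisjoint(m1))
    ## maximally merged: re-reducing is a no-op
    expect_identical(granges(sort(reduce(m1))), granges(sort(m1)))
  }
})

test_that("probes overlapping coding exons on the same strand are excluded", {
  mask <- GRanges("chr1", IRanges(c(101, 301), c(200, 400)), strand = "+")
  pt <- placedProbes(
    c("olap5bp", "oppStrand", "intronic"),
    "chr1",
    start = c(196L, 196L, 211L),
    end = c(220L, 220L, 235L),
    strand = c("+", "-", "+"))
  out <- probeStatus(filterProbesCoding(pt, mask))
  expect_equal(unname(out),
               c("coding_overlap", "unassigned", "unassigned"))
  bad <- ProbeTable("P1", paste(rep("A", 25), collapse = ""))
  expect_error(filterProbesCoding(bad, mask), "unassigned")
})

test_that("clustering joins same-strand exon overlaps transitively", {
  ## disjoint exons, same strand -> 2 clusters
  two <- c(mkTx(101, 200, id = "A"), mkTx(501, 600, id = "B"))
  expect_equal(length(clusterTranscripts(two)), 2L)
  ## A-B overlap, B-C overlap, A and C disjoint -> one cluster of 3
  chain <- c(mkTx(101, 200, id = "A"),
             mkTx(151, 300, id = "B"),
             mkTx(251, 400, id = "C"))
  cs <- clusterTranscripts(chain)
  expect_equal(length(cs), 1L)
  expect_equal(unname(unique(clusterMembership(cs))), "CL00001")
  ## identical coordinates, opposite strands -> 2 clusters
  opp <- c(mkTx(101, 200, id = "A"),
           mkTx(101, 200, strand = "-", id = "B"))
  expect_equal(length(clusterTranscripts(opp)), 2L)
  ## overlapping spans but disjoint exons (nested intron) -> 2 clusters
  nested <- c(mkTx(c(101, 901), c(200, 1000), id = "A"),
              mkTx(301, 700, id = "B"))
  expect_equal(length(clusterTranscripts(nested)), 2L)
})

test_that("clustering equals brute-force connected components", {
  withr::local_seed(41)
  for (rep in 1:25) {
    n <- sample(2:30, 1L)
    txl <- randomTxList(n)
    cs <- clusterTranscripts(asLncSet(txl))
    got <- unname(clusterMembership(cs))
    want <- oracleComponents(txl)
    ## same partition: equal co-membership matrices
    expect_identical(unname(outer(got, got, "==")),
                     unname(outer(want, want, "==")),
                     label = sprintf("partition (rep %d)", rep))
    expect_lte(length(cs), n)
  }
})

test_that("cluster ids are deterministic under input order", {
  withr::local_seed(43)
  txl <- randomTxList(20)
  ts <- asLncSet(txl)
  cs1 <- clusterTranscripts(ts)
  perm <- sample(20)
  cs2 <- clusterTranscripts(asLncSet(txl[perm],
                                     ids = sprintf("T%03d", perm)))
  expect_identical(granges(clusterRanges(cs1)), granges(clusterRanges(cs2)))
  m1 <- clusterMembership(cs1)
  m2 <- clusterMembership(cs2)
  expect_identical(m1[sort(names(m1))], m2[sort(names(m2))])
})

test_that("probe sets are the boundary-free segments of the footprint", {
  ## one transcript, no internal boundaries -> exons themselves
  cs <- clusterTranscripts(mkTx(c(101, 301), c(200, 400)))
  segs <- segmentProbesets(cs)
  expect_equal(start(segs), c(101L, 301L))
  expect_equal(end(segs), c(200L, 400L))
  expect_equal(segs$probeset_id, c("CL00001_PS001", "CL00001_PS002"))

  ## staggered overlap [101,200] + [151,250] -> three segments
  cs2 <- clusterTranscripts(c(mkTx(101, 200, id = "A"),
                              mkTx(151, 250, id = "B")))
  segs2 <- segmentProbesets(cs2)
  expect_equal(start(segs2), c(101L, 151L, 201L))
  expect_equal(end(segs2), c(150L, 200L, 250L))

  ## [101,200]+[301,400] against member [151,350] -> five segments
  cs3 <- clusterTranscripts(c(mkTx(c(101, 301), c(200, 400), id = "A"),
                              mkTx(151, 350, id = "B")))
  segs3 <- segmentProbesets(cs3)
  expect_equal(start(segs3), c(101L, 151L, 201L, 301L, 351L))
  expect_equal(end(segs3), c(150L, 200L, 300L, 350L, 400L))
})

test_that("segmentation matches the base-by-base labelling oracle", {
  withr::local_seed(47)
  for (rep in 1:40) {
    n <- sample(1:8, 1L)
    txl <- randomTxList(n, chroms = "chrA", maxStart = 800L, maxExons = 5L)
    for (i in seq_along(txl)) strand(txl[[i]]) <- "+"
    ts <- asLncSet(txl)
    cs <- clusterTranscripts(ts)
    segs <- segmentProbesets(cs)
    exdf <- do.call(rbind, lapply(seq_along(txl), function(i)
      data.frame(tx = sprintf("T%03d", i), start = start(txl[[i]]),
                 end = end(txl[[i]]))))
    want <- oracleSegments(exdf)
    got <- sort(ranges(segs))
    expect_identical(as.data.frame(got)[, 1:2],
                     as.data.frame(want)[, 1:2],
                     label = sprintf("segments (rep %d)", rep))
  }
})

test_that("segmentation boundaries grow monotonically with new members", {
  withr::local_seed(53)
  for (rep in 1:10) {
    txl <- randomTxList(4, chroms = "chrA", maxStart = 600L, maxExons = 4L)
    for (i in seq_along(txl)) strand(txl[[i]]) <- "+"
    before <- segmentProbesets(clusterTranscripts(asLncSet(txl[1:3])))
    after <- segmentProbesets(clusterTranscripts(asLncSet(txl)))
    ## every boundary present before (within the retained footprint)
    ## persists: old segment starts remain segment starts or lie outside
    ## the new footprint only if they never were inside it
    oldCuts <- sort(unique(c(start(before), end(before) + 1L)))
    newCuts <- sort(unique(c(start(after), end(after) + 1L)))
    expect_true(all(oldCuts %in% newCuts))
  }
})

test_that("probe assignment requires full same-strand containment", {
  cs <- clusterTranscripts(c(mkTx(101, 200, id = "A"),
                             mkTx(151, 250, id = "B")))
  segs <- segmentProbesets(cs)    # [101,150] [151,200] [201,250]
  pt <- placedProbes(
    c("inside", "straddle", "wrongStrand"),
    "chr1",
    start = c(120L, 140L, 122L),
    end = c(144L, 164L, 146L),
    strand = c("+", "+", "-"))
  ann <- assignProbes(pt, cs, segs)
  st <- probeStatus(probeTable(ann))
  expect_equal(unname(st[c("inside", "straddle", "wrongStrand")]),
               c("assigned", "unassigned", "unassigned"))
  expect_equal(probeData(probeTable(ann))$probeset_id[[1L]],
               "CL00001_PS001")
  ## only the populated probe set survives; the cluster keeps it
  expect_equal(probesetRanges(ann)$probeset_id, "CL00001_PS001")
  expect_equal(clusterRanges(ann)$n_probesets, 1L)
})

test_that("clusters whose probe sets are all empty are deleted", {
  cs <- clusterTranscripts(c(mkTx(101, 200, id = "A"),
                             mkTx(1001, 1100, id = "B")))
  segs <- segmentProbesets(cs)
  ## a probe only in the first cluster
  pt <- placedProbes("p1", "chr1", 110L, 134L, "+")
  ann <- assignProbes(pt, cs, segs)
  expect_equal(length(clusterRanges(ann)), 1L)
  expect_equal(length(ann@transcripts), 1L)
  expect_equal(txId(ann@transcripts), "A")
})

test_that("after assignment probe sets partition their probes", {
  withr::local_seed(59)
  for (rep in 1:5) {
    txl <- randomTxList(10)
    ts <- asLncSet(txl)
    cs <- clusterTranscripts(ts)
    segs <- segmentProbesets(cs)
    ## tile probes across segments (some deliberately straddling)
    pr <- GRanges()
    for (i in seq_along(segs)) {
      if (width(segs)[i] < 25L) next
      pr <- c(pr, GRanges(seqnames(segs)[i],
                          IRanges(start(segs)[i], width = 25L),
                          strand = strand(segs)[i]))
    }
    if (length(pr) == 0L) next
    pt <- placedProbes(sprintf("p%03d", seq_along(pr)),
                       as.character(seqnames(pr)), start(pr), end(pr),
                       as.character(strand(pr)))
    ann <- assignProbes(pt, cs, segs)
    d <- probeData(probeTable(ann))
    asg <- d[d$status == "assigned", ]
    expect_true(all(asg$probeset_id %in%
                      probesetRanges(ann)$probeset_id))
    expect_true(all(probesetRanges(ann)$n_probes >= 1L))
    expect_equal(sum(probesetRanges(ann)$n_probes), nrow(asg))
    ## probe sets disjoint within a strand
    for (str in c("+", "-")) {
      s <- probesetRanges(ann)[strand(probesetRanges(ann)) == str]
      expect_true(all(isDisjoint(split(ranges(s),
                                       as.character(seqnames(s))))))
    }
  }
})
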