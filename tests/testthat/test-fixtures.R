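## The generators are pure functions of their seeds; small genomes keep
## these tests quick while exercising every planted feature.

test_that("toy genomes are deterministic per seed and distinct across seeds", {
  g1 <- makeToyGenome(101, nChroms = 2L, length = 5000L)
  g2 <- makeToyGenome(101, nChroms = 2L, length = 5000L)
  g3 <- makeToyGenome(102, nChroms = 2L, length = 5000L)
  expect_identical(as.character(g1), as.character(g2))
  expect_false(identical(as.character(g1), as.character(g3)))
  expect_equal(length(g1), 2L)
  expect_equal(names(g1), c("chr1", "chr2"))
  ## planted repeats exist verbatim at both loci
  reps <- S4Vectors::metadata(g1)$repeats
  expect_gte(nrow(reps), 1L)
  s <- as.character(g1)
  for (i in seq_len(nrow(reps))) {
    w1 <- substring(s[[reps$src_chrom[i]]], reps$src_start[i],
                    reps$src_start[i] + reps$width[i] - 1L)
    w2 <- substring(s[[reps$dst_chrom[i]]], reps$dst_start[i],
                    reps$dst_start[i] + reps$width[i] - 1L)
    expect_identical(w1, w2)
  }
})

test_that("transcriptome generator controls overlap structure", {
  g <- makeToyGenome(7)
  ## no overlaps: clusters equal lncRNA count downstream
  t0 <- makeTranscriptome(8, g, overlapFraction = 0)
  lnc0 <- filterShortLncrnas(t0[which(txBiotype(t0) == "lncRNA")])
  expect_equal(length(clusterTranscripts(lnc0)), length(lnc0))
  ## full pairing: clusters at most half the lncRNA count... among the
  ## intergenic pool; overall strictly fewer clusters than transcripts
  t1 <- makeTranscriptome(8, g, overlapFraction = 1)
  lnc1 <- filterShortLncrnas(t1[which(txBiotype(t1) == "lncRNA")])
  cs1 <- clusterTranscripts(lnc1)
  expect_lt(length(cs1), length(lnc1))
  nPartners <- length(lnc1) - length(cs1)
  expect_gte(nPartners, floor(length(lnc1) / 2) - 7L)
  ## majority of lncRNAs are multi-exon
  nex <- S4Vectors::elementNROWS(exonRanges(lnc1))
  expect_gte(mean(nex > 1L), 0.6)
})

test_that("the fixture transcriptome exercises every positional category", {
  g <- makeToyGenome(7)
  txs <- makeTranscriptome(8, g)
  lnc <- filterShortLncrnas(txs[which(txBiotype(txs) == "lncRNA")])
  cod <- txs[which(txBiotype(txs) == "coding")]
  cls <- classifyClusters(clusterTranscripts(lnc), cod)
  expect_setequal(
    intersect(c("sense", "antisense", "intronic", "bidirectional",
                "extension", "close", "intergenic"), cls$category),
    c("sense", "antisense", "intronic", "bidirectional", "extension",
      "close", "intergenic"))
  ## short decoys present and filtered
  all_lnc <- txs[which(txBiotype(txs) == "lncRNA")]
  expect_gt(length(all_lnc), length(lnc))
  expect_true(all(splicedLength(lnc) > 200L))
})

test_that("probe-table truths are recovered by the mapper", {
  ## a genome too small for the layout stops the generator cleanly
  expect_error(makeTranscriptome(8, makeToyGenome(7, length = 20000L)),
               "genome")
  g <- makeToyGenome(7)          # full-size genome for the real check
  txs <- makeTranscriptome(8, g)
  tab <- makeProbeTable(9, g, txs)
  idx <- buildKmerIndex(g)
  mapped <- probeData(mapProbes(tab$probes, idx))
  truth <- tab$truth
  expect_identical(mapped$probe_id, truth$probe_id)
  ## planted multimapped and unmapped probes behave as planted
  expect_true(all(mapped$status[truth$planted == "multimapped"] ==
                    "multimapped"))
  expect_true(all(mapped$status[truth$planted == "unmapped"] ==
                    "unmapped"))
  ## tiled probes: those not hitting a duplicated window map uniquely to
  ## their intended locus
  ok <- truth$planted == "tiled" & mapped$status == "unassigned"
  expect_gt(mean(truth$planted == "tiled" & ok[seq_len(nrow(truth))]),
            0.9)
  expect_equal(mapped$start[ok], truth$start[ok])
  expect_equal(mapped$strand[ok], truth$strand[ok])
  ## same seed reproduces the table byte-identically
  tab2 <- makeProbeTable(9, g, txs)
  expect_identical(probeData(tab$probes), probeData(tab2$probes))
})

test_that("noise-free simulation gives constant probes and zero GNI", {
  ann <- tinyAnnotation()
  design <- groupDesign(paste0("s", 1:4), rep(c("A", "B"), each = 2))
  lin <- simulateIntensities(3, ann, design, tau = 0, sigma = 0)
  ## every probe constant across samples
  expect_true(all(apply(lin, 1L, function(x) max(x) - min(x)) == 0))
  res <- analyzeExpression(ann, lin, design)
  expect_true(all(abs(res$gni) < 1e-9))
  expect_true(all(res$splice$si == 0))
  ## same seed -> identical matrix
  expect_identical(lin, simulateIntensities(3, ann, design,
                                            tau = 0, sigma = 0))
})

test_that("planted splice and DE effects propagate to the simulation", {
  ann <- tinyAnnotation()
  design <- groupDesign(paste0("s", 1:6), rep(c("A", "B"), each = 3))
  sp <- data.frame(probeset_id = "CL00001_PS004", delta = 2, group = "A")
  de <- data.frame(cluster_id = "CL00002", delta = 3, group = "B")
  lin <- simulateIntensities(5, ann, design, spliceEffects = sp,
                             deEffects = de, tau = 0, sigma = 0)
  l2 <- log2(lin)
  pToPs <- probeToProbeset(ann)
  hit <- names(pToPs)[pToPs == "CL00001_PS004"]
  expect_equal(unname(l2[hit, "s1"] - l2[hit, "s4"]), rep(2, length(hit)))
  cl2 <- names(pToPs)[probesetToCluster(ann)[pToPs] == "CL00002"]
  expect_equal(unname(l2[cl2[1], "s4"] - l2[cl2[1], "s1"]), 3)
})

test_that("the fixture workspace is complete and generators are seeded", {
  d <- withr::local_tempdir()
  fx <- makeFixtureWorkspace(d, seed = 1234)
  expect_true(all(file.exists(fx$paths)))
  ## every probe status occurs in the built annotation
  st <- probeStatus(probeTable(fx$annotation))
  expect_setequal(unique(unname(st)),
                  c("unmapped", "multimapped", "coding_overlap",
                    "unassigned", "assigned"))
  ## at least one cluster with >= 3 probe sets from overlap segmentation
  expect_gte(max(table(probesetRanges(fx$annotation)$cluster_id)), 3L)
  ## at least one cluster deleted by the empty-probe-set rule: the
  ## fully-coding-overlapping sense lncRNA leaves the annotation
  kept <- txId(fx$annotation@transcripts)
  expect_lt(length(kept), fx$truth$summary[["lncrna_after_length_filter"]])
})
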