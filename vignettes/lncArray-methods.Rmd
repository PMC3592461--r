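---
title: "lncArray: methods and design notes"
author: "lncArray authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{lncArray: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lncArray)
```

# Background

Affymetrix exon arrays tile ~25-nt probes across the full length of a
gene rather than only its 3' end. The vendor annotation organises those
probes on two levels: all isoforms of a gene are combined into a
*transcript cluster* (the gene-level unit), and each exonic segment of
the cluster is a *probe set* (the exon-level unit, usually ~4 probes).
Most of the probes on the chip, however, target ESTs and predicted
transcripts that the curated protein-coding annotation ignores. lncArray
rebuilds the two-level scheme for long non-coding RNAs (lncRNAs), so
that both lncRNA gene expression and lncRNA exon expression — and hence
alternative splicing of lncRNAs — can be measured on existing exon-array
data.

# The annotation procedure

The pipeline (`buildAnnotationPipeline()`) runs seven steps:

1. **Probe mapping.** Probes are placed on the genome by exact matching
   with zero mismatches: a k-mer index of every forward-strand genome
   window of probe length is queried with the probe sequence (forward
   hits) and its reverse complement (reverse hits). Probes with no hit
   or more than one hit across both strands are discarded. A
   reverse-complement-palindromic probe matching a single locus counts
   both strand alignments and is therefore discarded as multi-mapping —
   the conservative reading of what a zero-mismatch aligner reports.
   `N` in the genome never matches any base.
2. **Coding-exon exclusion.** The exons of all protein-coding
   transcripts from all supplied annotation sources are merged into a
   per-strand mask; every uniquely mapped probe overlapping the mask on
   the *same strand* by at least 1 bp is excluded. Probes antisense to a
   coding exon, or inside a coding intron, are kept — introns are not
   exons, and exon arrays are strand-specific.
3. **Length filter.** lncRNAs with a spliced length (sum of exon
   lengths, not genomic span) of 200 nt or shorter are discarded; 200 nt
   is the conventional lower bound of the lncRNA class.
4. **Clustering.** lncRNAs that overlap each other on the same strand
   are combined into transcript clusters: connected components of the
   graph whose edges join same-strand transcript pairs sharing at least
   1 bp of *exon*. Overlap is exon-level, not span-level, so a
   transcript nested inside another's intron without shared transcribed
   sequence stays separate. Abutting exons (gap 0) do not connect.
5. **Segmentation.** Within each cluster, probe sets are the maximal
   sub-intervals of the exonic footprint (union of member exons) whose
   interiors contain no exon boundary of any member: contiguous regions
   not interrupted by exon boundaries. Where two members overlap with
   staggered ends, each distinct combination of covering transcripts
   becomes its own probe set, which is what makes isoform-resolved exon
   signals possible.
6. **Probe assignment.** A probe is assigned to a probe set when its
   alignment is fully contained in the probe-set interval on the same
   strand. Probes straddling a probe-set boundary are dropped: a
   straddling probe would mix the signal of two exonic parts.
7. **Pruning.** Probe sets without probes are deleted, and clusters left
   without probe sets are deleted in turn. This also removes lncRNAs
   that lie entirely within protein-coding exons, whose probes were all
   excluded in step 2.

Cluster identifiers are assigned deterministically (sorted by
chromosome, strand, span start), so identical inputs give byte-identical
annotation files.

## Positional classification

Each retained cluster is classified relative to protein-coding genes
(`classifyClusters()`) into one of seven categories, evaluated in a fixed
precedence order that turns overlapping definitions into a partition:
**sense** (exon overlap, same strand) > **antisense** (exon overlap,
opposite strand) > **intronic** (span entirely within one intron, no
exon overlap, either strand) > **bidirectional** (non-overlapping,
opposite strand, 5' ends facing each other across a gap under the
proximity threshold — divergent-promoter geometry) > **extension**
(non-overlapping, same strand, proximate) > **close** (non-overlapping,
opposite strand, proximate, not head-to-head) > **intergenic**. The
proximity threshold is 1000 bp, strictly: a gap of exactly 1000 bp is
not proximate, and "head-to-head" requires the left-hand element on the
minus strand and the right-hand element on the plus strand. The
reported distance is the minimal gap to the nearest gene span (0 when
spans overlap). Gene spans are the union of each gene's transcripts;
without gene grouping every coding transcript is its own gene. These
precedence and geometry choices are this package's own: the category
definitions do not state an order, and any fixed order that puts
overlap before proximity yields a well-defined partition.

# Expression model

Let $I_{is}$ be the linear intensity of probe $i$ in sample $s$. The
summarisation pipeline is an RMA without background correction
(background modelling belongs to the array pre-processor, not to this
method): $\log_2$ transform, quantile normalisation across samples
(ties receive the mean of their target quantiles), then Tukey median
polish of each feature's probes-by-samples matrix into overall + probe
+ sample effects. The per-sample feature summary is overall + sample
effect. Median polish runs at most 10 sweeps or until the change drops
below $10^{-6}$; on exactly log-additive data it converges in one sweep
with zero residuals. Ties in medians use the standard sample median
(mean of the two central values), the convention of `stats::medpolish`
and of RMA summarisation.

The **cluster signal pools all retained probes of the cluster**, not
the mean of probe-set summaries — mirroring the meta-probe-set design in
which the gene-level estimate uses every probe of the transcript
cluster. With $e_{ps}$ the log2 probe-set summary and $g_{cs}$ the log2
summary of probe set $p$'s cluster $c$:

$$\mathrm{GNI}_{ps} = e_{ps} - g_{c(p),s}$$

is the *gene-level normalised intensity*: the exon-specific signal with
the gene-level signal removed. For a two-group design the **Splice
Index** is the difference of group means of GNI,

$$\mathrm{SI}_p = \overline{\mathrm{GNI}}_{p,\mathrm{g1}} -
  \overline{\mathrm{GNI}}_{p,\mathrm{g2}},$$

i.e. the log2 fold change of exon-specific signal; a non-zero SI flags
differential exon usage. GNI is computed per sample and then averaged
per group (the log fold change of GNIs), not as a ratio of group
averages. Per-probe-set p-values come from a Welch two-sample t-test on
the per-sample GNI values, and cluster-level differential expression
uses the same test on the cluster summaries; both are corrected by
Benjamini–Hochberg across their result set. The Welch t replaces the
moderated t of dedicated microarray linear-model software: the
moderated-variance machinery is external statistical tooling, not part
of this method, and the contract (per-feature fold change, p, FDR) is
unchanged. A zero-variance feature with equal group means gets p = 1
and fold change 0 rather than an error. For heat-map-style overviews,
`selectTopVariance()` keeps the n most variable features (default 150,
the conventional panel size for tissue clustering).

## Parameters

| parameter | default | units | role |
|---|---|---|---|
| `probeLength` | 25 | nt | platform probe length; word length of the genome index |
| `minSplicedLength` | 201 | bp | minimum spliced length kept (discard "200 nt or shorter") |
| `proximateDistance` | 1000 | bp | strict upper bound on a "proximate" gap |
| `minProbesPerSet` | 1 | probes | probe sets below this are pruned (default deletes only empty sets) |

# The synthetic-fixture model

Every test input is generated by seeded code (`makeToyGenome()`,
`makeTranscriptome()`, `makeProbeTable()`, `simulateIntensities()`);
generators are pure functions of their seed, so reruns are
byte-identical. The toy genome is uniform random ACGT (default two
chromosomes of 150 kb) with a few 25-bp windows duplicated into a
reserved tail zone to provide known multi-mapping probes. The
transcriptome places protein-coding genes (3–5 exons) in regular slots
and anchors lncRNAs around them so that every positional category
occurs, including a lncRNA lying entirely within coding exons whose
cluster is later deleted by the empty-probe-set rule, and short (≤200
nt) decoys for the length filter. A configurable fraction of lncRNAs is
drawn as same-strand overlapping partners with staggered exon
boundaries, which makes their clusters segment into three or more probe
sets. At least 60% of lncRNAs are multi-exon, matching the
multi-exon-dominated composition of curated lncRNA catalogues. Probes
are 25-mers copied from the genome at 35-bp offsets within exons on the
transcript's sense strand, plus planted multi-mapping and non-genomic
(verified absent on both strands) probes.

Intensities follow a log-additive Gaussian model:

$$\log_2 I_{is} = \mu + a_i + b_{c(i)} + \delta_{\mathrm{de}}(c(i), s)
  + \delta_{\mathrm{sp}}(p(i), s) + \varepsilon_{is},$$

with baseline $\mu = 8$, probe affinities $a_i \sim N(0, \tau^2)$
($\tau = 0.5$), cluster baselines $b_c \sim N(0, 1)$, planted
cluster-level and probe-set-level group effects, and noise
$\varepsilon \sim N(0, \sigma^2)$ ($\sigma = 0.25$). This is the
simplest model under which median polish is a consistent summary;
heavier-tailed noise, cross-hybridisation and GC affinity bias are
deliberately out of scope. Consequently, passing tests demonstrate the
correctness of the interval algebra and the statistical contracts under
the stated model — they do not certify performance on real CEL-derived
intensities, where background and sequence-dependent affinity effects
require the array pre-processor the model omits.

The statistical recovery study uses the generator defaults: 5 vs 5
samples, one probe set of a multi-probe-set cluster carrying a planted
+2.0 log2 splice effect with cluster-level expression equal between
groups, 100 seeded replicates, and a matching null study (no effect)
for the type-I error of the probe-set Welch test. The recovered SI is
slightly attenuated relative to the planted effect because the affected
probes also enter the cluster summary (and quantile normalisation
compresses extreme shifts at toy scale); with the affected probe set a
minority of its cluster the attenuation is small.

# Numerical and design choices

* **Coordinates.** In memory all intervals are `GRanges`/`IRanges`
  (1-based, closed), the native Bioconductor convention; BED files on
  disk are 0-based half-open, with conversion handled by `rtracklayer`.
  All overlap, containment and gap computations are convention-free.
* **Tie-breaks and determinism.** Cluster and probe-set identifiers
  derive from coordinate-sorted order only; probe input order never
  affects mapping results; ties in the top-variance selection resolve
  to first occurrence.
* **Degenerate inputs.** Empty transcript sets, empty clusters and
  single-probe features are legal everywhere (a single-probe feature
  summarises to that probe); a single-sample matrix passes quantile
  normalisation unchanged with a warning; zero-variance features yield
  p = 1 / fc = 0 when means agree.
* **Problem sizes.** The oracle-equivalence checks run at 1000 random
  clusters (segmentation), 200 instances of up to 50 transcripts
  (clustering) and 50 random 20-kb genomes with 500 probes each
  (mapping); the statistical studies use 100 replicates each for
  recovery and null calibration. These sizes give exhaustive coverage
  of the combinatorics at desk scale while keeping the default test run
  comfortably fast.

# Known limitations

* Mapping is exact-match only: no mismatches, indels or spliced
  alignment, by construction of the zero-mismatch contract.
* Only two-group unpaired designs are supported; no batch correction,
  detection calls, or multi-factor models.
* The classifier reports one category per cluster under a fixed
  precedence; a cluster that is, e.g., both antisense to one gene and
  proximate to another reports only the higher-precedence category.
* Real-array effects (background, GC bias, cross-hybridisation) are
  outside the intensity model; see the fixture section above.
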