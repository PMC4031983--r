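---
title: "Methods: screen hit calling, LOH classification and locus association"
author: "mirLOH"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: screen hit calling, LOH classification and locus association}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirLOH)
```

## What the package computes

mirLOH implements two linked analyses around miRNAs that suppress
homologous-recombination (HR) repair. HR completed in G1 can resolve as
mitotic recombination, which produces *copy-neutral* loss of
heterozygosity (LOH): both copies of a region derive from one parental
allele while total copy number stays at two. Deletions produce LOH of a
different kind — one allele is physically lost. If a miRNA restrains HR,
tumors that have deleted its locus should show an excess of LOH and of
genomic instability generally, and higher expression of its targets
(BRCA1). The package therefore provides:

1. **Screen analysis** — calling miRNA mimics that sensitize cells to a
   PARP inhibitor from multi-well luminescence plates.
2. **Cohort analysis** — classifying tumor LOH events as
   deletion-mediated vs copy-neutral, genotyping the three miRNA loci
   (miR-1255b at its two genomic copies, miR-148b*, miR-193b*), and
   comparing per-sample burdens between WT and deletion groups.
3. **A synthetic-data generator** that plants all of the above with
   known truth, so every stage is testable without external data.

## Screen model

Each plate carries negative-control mimic wells, BRCA2-siRNA
positive-control wells and library-mimic wells, measured in a drug arm
and a vehicle arm. Normalisation is per plate and per arm against the
negative controls with mean $\mu$ and sample standard deviation
$\sigma$:

$$ z = \frac{x - \mu}{\sigma}, \qquad
   \%\,\text{viability} = 100 \cdot \frac{x}{\mu}. $$

A mimic is **toxic** when its vehicle-arm percent viability is less
than or equal to that of the BRCA2-siRNA control on its plate (equality
counts as toxic); toxic mimics kill cells without the drug and are not
considered. A **hit** is a non-toxic mimic with drug-arm $z < -2$ and
drug-arm viability $< 75\%$ of control. Hits are ranked by ascending
drug-arm viability, with ties broken by ascending $z$ and then by mimic
identifier. Two readings of the Z cutoff coexist in common practice —
a fixed constant and the per-plate Z of the BRCA2-siRNA control; the
constant $z < -2$ is the default because it is reproducible across
plates, and `zMode = "brca2"` selects the comparator reading.

Replicate wells ("triplicates" in a standard screen) are averaged per
mimic and arm *after* per-replicate normalisation and before
thresholding; `replicates = "raw"` exposes the per-replicate table. The
`foldEnrichment()` helper computes the pull-down double ratio
$(\text{pd}_{miR}/\text{pd}_{ctl}) / (\text{in}_{miR}/\text{in}_{ctl})$
used to quantify target capture by a biotinylated miRNA.

## LOH classification rules

Two platform-specific rules are implemented, with every inequality
fixed as printed in the thresholds' source conventions:

**Segment (aCGH) rule.** Deletion segments are copy-number segments
with log2 ratio strictly below $-0.20$. An LOH event is
*deletion-mediated* when such segments cover at least 80% of its length
(non-strict, union across segments so overlaps are not double-counted);
all other events are *copy-neutral*. Copy-neutral events are retained
for burden counting only when strictly longer than 1 Mb.

**Marker (SNP) rule.** Events at or below 10 kb are dropped before
counting (strictly greater sizes pass). For each remaining event, $N$
counts markers inside it and $n$ counts those with allelic copy number
strictly below 1.9. The event is deletion-mediated iff $n/N \ge 0.8$
(non-strict), otherwise copy-neutral. Events with $N = 0$ stay
unlabelled and are excluded with a logged warning — the rule is
undefined there and guessing would bias the copy-neutral count. A
sensitivity rerun with the cutoff at 0.75 is one parameter away
(`analysisParams(snpFracCutoff = 0.75)`); since lowering the cutoff can
only relabel copy-neutral events as deletion-mediated, the 0.8 set is
always contained in the 0.75 set, which the tests assert.

Coordinates are held in `GRanges`, i.e. 1-based closed intervals; BED
input is converted on import and SEG-like TSV maps one-to-one. Event
length is the `GRanges` width, and a marker sitting exactly on an event
boundary is inside the (closed) event interval. These conventions are
deliberately single-sourced in the container rather than re-derived per
operation.

## Locus genotyping and groups

Under the segment rule, a locus takes the log2 value of the segment
overlapping its midpoint (loci are 62–83 bp, so they essentially never
straddle segment boundaries; should several segments overlap the
midpoint the narrowest wins, ties to the lower start). Status is
deletion below $-0.2$, neutral in the closed band $[-0.2, 0.2]$,
amplification above, unknown with no covering segment. Under the marker
rule the nearest marker on the locus chromosome decides (distance zero
inside; equidistant ties break to the lower genomic position —
deterministic and covered by a brute-force oracle test), with the
closed neutral band $[1.9, 2.1]$ on allelic copy number.

Mature miR-1255b comes from two loci; its combined status is deletion
when either locus is deleted, then amplification if either is
amplified, neutral only when both are neutral, unknown otherwise. A
sample is **WT** only when all three miRNAs are neutral; it enters the
deletion group of each deleted miRNA (groups are not mutually
exclusive, matching per-miRNA comparisons against a common WT
baseline); amplification-only or unknown-bearing samples are excluded.
Only the two miR-1255b loci have published coordinates
(`printedMirnaLoci()`); miR-148b* and miR-193b* intervals must come
from the user's annotation, and `syntheticMirnaLoci()` supplies
documented synthetic stand-ins for simulation work.

## Association testing

Each deletion group is compared against WT with a one-tailed
Mann–Whitney U test in the fixed direction "deletion greater" — the
hypothesis is directional (loss of an HR-suppressing miRNA increases
LOH burden, copy-number aberration burden and BRCA1 expression), so the
direction is not estimated from the data. $U$ is computed from midranks.
The p-value $P(U \ge u)$ uses three regimes, locked by oracle tests:

* no ties and $n_a n_b \le 400$: the exact null distribution;
* ties and $n_a + n_b \le 12$: full enumeration of all
  $\binom{n_a+n_b}{n_a}$ group assignments;
* otherwise: normal approximation with continuity and tie correction.

When every value in both groups is identical the test is uninformative
and $p = 0.5$ is returned with a warning. No multiple-testing
correction is applied across the three miRNA groups by default (none is
used in the reference analysis); `bonferroni = TRUE` enables one.

The burden metrics are: retained copy-neutral LOH events per sample;
somatic copy-number events per sample (out-of-band segments, with
consecutive same-sign out-of-band segments of one chromosome's
segmentation merged into one event); and per-gene expression values
taken as provided.

## The synthetic cohort: what it emulates, and what it does not

`simulateCohort()` plants, per sample, on a four-chromosome model
genome (chr1/chr4/chr12/chr16 at realistic lengths, carrying the three
loci):

* **Reportable copy-neutral LOH** events (> 1 Mb, log-uniform up to
  10 Mb) at Poisson rate 60 per WT sample and 80 per deletion-group
  sample. These defaults mirror the scale of real serous ovarian
  cohorts, where on the order of 26,000 events over ~420 samples gives
  roughly 60 reportable events per sample; the rate parameters are
  defined on *reportable* events so the group effect is not diluted by
  the size filter. Sub-threshold copy-neutral events (1 kb–1 Mb,
  rate 15) are added identically in all groups so both size filters are
  exercised on both sides.
* **Deletion-mediated LOH** events (rate 20, 1 kb–10 Mb, all groups)
  co-located with one or two aCGH deletion segments covering a fraction
  drawn from $[0.85, 1]$ — deliberately clear of the 0.80 cutoff so
  planted labels are non-borderline; boundary semantics are pinned
  separately by the hand-built `boundaryFixtures()`. All markers inside
  such an event are drawn low (≈1.2), as expected when one allele is
  lost.
* **Extra somatic copy-number events** (rates 30 WT / 40 deletion
  groups) and, for each deletion-group sample, a 0.2–2 Mb focal
  deletion covering its miRNA locus (one of the two miR-1255b loci at
  random).
* A regular **marker grid** (25 kb spacing — a deliberately thinned
  stand-in for a 1M-probe array, keeping a full cohort under two
  million marker values) with baseline allelic copy number
  $\mathcal{N}(2.0, 0.02)$, and **BRCA1 expression**
  $\mathcal{N}(8, 1)$ shifted up by 1 in deletion groups.

Placement is rejection-sampled so that copy-neutral events never
overlap deletion territory, extra copy-number events never overlap LOH
events, and nothing but the planted focal deletion approaches a miRNA
locus (±100 kb). Gaps between planted segments are filled with neutral
baseline segments, giving each sample a non-overlapping per-chromosome
segmentation. A single root seed drives deterministic per-stage child
seeds, so any layer is reproducible in isolation.

The generator does **not** emulate allele-specific intensity noise, GC
waves, segmentation errors, overlapping LOH calls within a sample, or
borderline coverage fractions (except on request via the boundary
fixtures). Passing the recovery tests therefore demonstrates that the
decision rules are implemented exactly as stated — not that they are
robust to array artefacts, which are upstream of this package's inputs.

The screen generator follows the same philosophy: well luminescence is
`base × plate-scale × effect × log-normal noise` with mean-one noise of
10% CV, 16 negative-control and 4 BRCA2-siRNA wells per 384-well plate,
three replicates, and planted drug-arm-only hits (effect 0.5) plus
drug-independent toxic mimics (effect 0.5 in both arms, at the
BRCA2-siRNA vehicle level so the toxicity filter must catch them).
Sixteen controls per plate is a standard screen layout and keeps the
$\sigma$ estimate stable enough that the dual hit threshold yields no
false positives at 880 mimics.

## Numerical and design choices

* **Strict vs non-strict boundaries** follow the printed wording
  everywhere: log2 $< -0.20$ strict; coverage $\ge 80\%$ non-strict;
  sizes $> 1$ Mb / $> 10$ kb strict; $n/N \ge 0.8$ non-strict; allelic
  copy number $< 1.9$ strict; both neutral bands closed; toxicity
  "equal or more" non-strict.
* **Union coverage** across deletion segments (not best-single-segment
  overlap): "overlapped with deletion events" is plural, union is the
  conservative reading, and it is the one a per-base oracle can verify.
* **Exact-vs-approximate switchover** for the U test at
  $n_a n_b \le 400$ (untied) and $n_a+n_b \le 12$ (tied) trades
  determinism against cost and is locked by enumeration tests.
* Problem sizes in the tests (cohorts of 70 samples, 100 power
  replicates, 200 null replicates, 10,000 coverage instances) were
  chosen to estimate each property comfortably within a routine test
  run while leaving Monte-Carlo error far from the asserted margins.
* The classification, genotyping and association stages are pure
  functions of their inputs; `runPipeline()` writes outputs only after
  all stages succeed, so a failure leaves no partial files.

## Known limitations

* The two-library merge of a real screen (confirming one library's
  hits in the other) is exposed only as a join of result tables; the
  package does not threshold cross-library confirmation.
* The marker-rule pipeline cannot label events without markers; with
  sparse grids this silently (but loggedly) shrinks the copy-neutral
  set.
* Mature miRNA sequences for the duplex utilities, and real locus
  coordinates for miR-148b*/miR-193b*, must be supplied by the user;
  the package ships only synthetic stand-ins for simulation.
* `fold enrichment` and the duplex utilities are deliberately minimal:
  no thermodynamic scoring, no genome-wide target scanning.
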