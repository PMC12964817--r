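---
title: "Genotyping a structural variant from a local pangenome graph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genotyping a structural variant from a local pangenome graph}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panloc)
```

## The problem

Some trait-associated structural variants (SVs) sit in repeat-dense
regions where short reads cannot be assembled or even mapped uniquely
against a linear reference. A *local pangenome* sidesteps this: the
region of interest is cut out of many long-read assemblies, the
extracted sequences are collapsed into a variation graph whose nodes are
shared or variant sequence segments and whose embedded paths spell each
assembly's haplotype, and short-read cohorts are then genotyped by how
deeply their reads cover the variant part of the graph. The motivating
use case is a multi-kilobase insertion of repeated units upstream of a
pigmentation gene, carried dominantly by white-headed cattle breeds and
absent in color-headed ones, with a nearby chromosome 6/29 serial
translocation (color-sidedness) as a second structural signal.

`panloc` implements the downstream analysis of that design as a tested,
reusable pipeline. Alignment and graph construction themselves
(minimap2, pggb, vg giraffe) are deliberately out of scope: the package
consumes their standard interchange formats (PAF, GFA, GAF) and, for
validation, generates all three from a synthetic truth model.

## Pipeline at a glance

1. **Interval projection** (`parsePaf()`, `projectInterval()`): the
   reference interval of interest is projected through assembly-vs-
   reference alignments into contig coordinates, walking the `cg` CIGAR
   when present.
2. **Contig admission** (`admitAdditionalContigs()`): contigs that reach
   the target region from elsewhere in the genome ("additional"
   sequences) are admitted only if the aligned segment is >= 10 kb and
   covers >= 80% of the contig. Both thresholds are parameters; the
   defaults are the published filter.
3. **Translocation signatures** (`detectTranslocationSignatures()`):
   contigs whose alignment blocks span several chromosomes, or whose
   same-chromosome blocks are out of reference order, are flagged with
   their ordered block structure.
4. **Graph model** (`parseGfa()`, `pathNodeDepth()`,
   `classifyNodes()`): per-node traversal multiplicity and per-node
   sample depth; nodes are core (all samples), variable (a subset) or
   private (one sample).
5. **Subregion detection** (`detectDifferentialSubregions()`): variable
   nodes sharing an identical carrier-sample set are grouped along a
   backbone path into SV candidate calls.
6. **Read-depth genotyping** (`accumulateNodeCoverage()`,
   `estimateSampleDepth()`, `normalizedRegionCoverage()`,
   `callGenotype()`): per-node aligned bases from GAF, normalized over
   both sequencing depth and region length.
7. **Association** (`breedCarrierSummary()`, `fisherExactTwoSided()`,
   `dominanceConcordance()`).

`runEndToEnd()` composes stages 1-7 on a simulated cohort and writes
every stage's outputs plus a JSON summary.

## The normalization and genotype model

For a sample $s$ and a node set $R$ defining the variant region, the
raw per-base coverage is

$$ c_s(R) \;=\; \frac{\sum_{v \in R} b_{s,v}}{L_R}, $$

where $b_{s,v}$ is the number of aligned bases sample $s$ placed on
node $v$ and $L_R$ is the region length. The normalized coverage is
$\hat c_s(R) = c_s(R) / d_s$ with $d_s$ the sample's sequencing depth,
so a region present on both haplotypes sits near 1.0, a heterozygous
region near 0.5, and a duplicated region above 1.5 — the diploid band
0.50–1.50 used to sanity-check short-read panels.

Two choices here were genuinely open and deserve explanation:

* **The depth denominator.** Published descriptions of this
  normalization rarely state whether depth is genome-wide or local.
  `estimateSampleDepth()` defaults to the *median per-base coverage
  over the core nodes of the analyzed subgraph*: it is self-contained
  (no genome-wide BAM needed), robust to the SV itself (SV nodes are
  not core) and to occasional outlier nodes (median, not mean). A
  numeric override is accepted whenever an external estimate is
  preferred.
* **The region length $L_R$ for repeat insertions.** When an insertion
  is a tandem run of `k` identical units, the graph collapses the unit
  to one node that carrier paths traverse `k` times. Summing plain node
  lengths would understate $L_R$ by a factor `k` and inflate $\hat c$
  accordingly. Subregion calls therefore report the *walk length* —
  node length times the median traversal multiplicity among carrier
  paths — and genotyping passes that as `regionLength`. With this
  convention heterozygotes land at 0.5 and homozygotes at 1.0
  regardless of `k`, and the copy-number estimate
  $\mathrm{round}(2\hat c)$ counts alleles.

Genotypes are called from $\hat c$ with thresholds placed symmetrically
around the expected states: `absent` below 0.25, `het` in [0.25, 0.75),
`hom` in [0.75, 1.5), `dup` at and above 1.5. The upper band edge
matches the diploid band's printed upper limit; all three thresholds
are user-configurable, boundaries fall deterministically in the upper
class, and copy numbers use R's half-even rounding.

## Subregion detection as an algorithm

The original analyses of this kind located the variant region by eye in
a graph viewer. Reproducibility requires an algorithm, so `panloc`
replaces inspection with a deterministic rule: every traversed non-core
node has a *carrier signature* (the sorted set of samples traversing
it); nodes with identical signatures are ordered along a designated
backbone path and merged when at most `maxGap` (default 5) backbone
nodes intervene; a group becomes a call when its walk length reaches
`minTotalLen` (default 1 kb, below which indel noise dominates) and its
carrier count reaches `minCarriers` (default 2, excluding
assembly-private artifacts such as the node classes attributed to
pseudo-haploid assembly errors). Calls are ranked by walk length with
ties broken by smallest backbone position. Nodes absent from the
backbone (the inserted sequence itself) inherit the backbone position
of their nearest neighbour by breadth-first search, which keeps the
procedure well-defined on non-DAG graphs.

Sample identity is the path-name prefix before `#` (PanSN style), so
the two haplotypes of one diploid sample count once toward node depth
while their traversal multiplicities remain visible for copy-number
work — this is what makes pseudo-haploid and haplotype-resolved
assemblies comparable in one graph.

## What the simulator emulates — and what it does not

`simConfig()` / `simulateHaplotypes()` build a cohort with known truth:

* a random 30 kb backbone shared by all haplotypes (the size of the
  subregion this analysis targets);
* an SV allele made of 3 identical 2.3 kb units (~7 kb total) inserted
  at the backbone midpoint on carrier haplotypes — modelling the
  variant as repeated units, not divergent sequence, so that copy
  number manifests as elevated coverage on shared nodes;
* carrier zygosity drawn per sample (default het/hom 50:50),
  non-carriers without the insertion; phenotype is white if and only if
  at least one carrier haplotype is present (strict dominance);
* private substitution SNPs per haplotype (rate 5e-4/bp) so the graph
  has realistic private nodes;
* single-end 150 bp reads placed uniformly at depth/2 per haplotype
  (Poisson read counts, default 30x per sample) with substitution
  errors at 1e-3 — truth GAF records are the exact sub-walk of the
  haplotype path, so errors never change placement.

One master seed drives everything; per-sample sub-seeds are derived as
seed + sample index, so enlarging a cohort leaves existing samples
byte-identical. `emitTruthGraph()` converts the known compositions
into a GFA graph (this *replaces* graph induction from alignments,
which is out of scope), `emitPaf()` writes the implied assembly
alignments, and `simulateTranslocationContig()` builds a toy
two-chromosome reference plus a contig with the serial-translocation
block order (acceptor flank, donor segment DE, donor segment AD,
acceptor flank) and a colinear control.

Passing tests on this generator demonstrate that the *computational
chain* is correct: coordinates, conservation laws, normalization
algebra, threshold logic, and recovery of a planted signal at realistic
depth. They do not demonstrate robustness to what the generator leaves
out: alignment ambiguity in repeats, indel and quality-profile error
structure, reference bias in read-to-graph mapping, assembly errors
other than haplotype sampling, or population structure beyond a binary
carrier/non-carrier split. Results on real cohorts inherit the error
characteristics of the upstream aligners.

## Numerical and degenerate-input choices

* Coordinates are 0-based half-open throughout (PAF/BED convention);
  region strings like `"6:69000000-71000000"` are 1-based inclusive and
  converted at the boundary by `parseRegion()`. `intervalLength()` is
  `end - start`, so printed coordinate pairs of segments give their
  published sizes directly.
* Projections without a CIGAR fall back to proportional interpolation
  and are marked `approximate` — visible, never silent.
* Aligned length for admission is the union of image intervals;
  overlapping alignments are not double-counted. One published
  admission (29,216 of 39,067 bp, 74.8%) contradicts the stated 80%
  rule; the implementation follows the rule and reports the failing
  fraction in its `reason` column rather than reproducing the table
  row.
* The exact test uses the minimum-likelihood two-sided rule with a
  1e-7 relative tolerance when comparing point probabilities, which
  makes p-values platform-stable; the odds ratio applies the +0.5
  Haldane–Anscombe correction only when a cell is zero, and flags it.
* Zero-coverage samples yield depth 0 and a hard error at
  normalization, not a silent NaN; empty cohorts, empty node sets and
  all-zero contingency tables are errors.
* Best-alignment filtering breaks full ties by mapping quality, then by
  lexicographically smallest path string — deterministic across runs
  and input orders.

## Worked example

```{r demo, eval = FALSE}
library(panloc)
cfg <- runConfig(outputDir = "panloc_demo", seed = 1, writeReads = FALSE)
summary <- runEndToEnd(cfg)
summary$subregion$totalLength     # 6900 bp: the planted 3 x 2.3 kb insertion
summary$association$concordance   # 1: calls match simulated truth
summary$association$p             # ~1e-11: carrier status vs phenotype
```

The default demo (40 samples at 30x, seed 1) runs in well under two
minutes on one CPU; the suite's property checks use the same
configuration with 10 seeds for genotype recovery and 20 seeds for
subregion recovery, sizes chosen so the whole validation remains a
coffee-break computation while the binomial uncertainty on the reported
rates stays a few percent.

## Known limitations

* Subregion detection requires an exact carrier-set match across the
  variant's nodes; heavily nested or overlapping SV alleles sharing
  nodes would fragment into several calls.
* Traversal-multiplicity-based walk lengths assume carrier paths agree
  on copy number; mixed copy numbers report the median.
* The Fisher test is exact but unadjusted: stratification or kinship in
  real cohorts calls for mixed-model follow-up, which is out of scope.
* `runEndToEnd()` in real-input mode runs only the stages whose inputs
  are supplied (projection needs a PAF and region; genotyping needs
  per-sample GAFs; association needs a phenotype table) — it never
  guesses missing inputs.
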