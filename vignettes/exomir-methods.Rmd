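---
title: "Methods: exosomal small-RNA cargo-sorting analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: exosomal small-RNA cargo-sorting analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exomir)
library(dplyr)
```

exomir re-implements, as composable tibble-in/tibble-out functions, the
analysis used to compare small-RNA cargo of exosomes against their parent
cells in colorectal cancer lines that differ only in *KRAS* status
(mutant DKO-1, wild-type DKs-8, parental DLD-1). This vignette explains
the procedures, the parameters that matter, what the synthetic-data
generator does and does not emulate, and the numerical choices made where
the underlying methods descriptions left the design open.

## The pipeline at a glance

1. **Read preparation** — 3' adapter trimming at a maximum error rate of
   0.1 per matched adapter base, then exclusion of reads shorter than
   15 nt.
2. **Mapping and annotation** — ungapped alignment (no indels, bounded
   substitutions, best stratum only), multi-mapper weighting at `1/k`,
   and hierarchical classification into miRNA / tRNA / rRNA / snRNA /
   repeat / other ncRNA, with mature-miRNA windows extended by 2 nt on
   both sides to accommodate imprecise precursor processing.
3. **isomiR classification** — iterative trim-and-remap: a read that maps
   neither hairpins nor genome is trimmed 1 nt from its 3' end and
   remapped to hairpins, up to 10 times; the removed suffix is resolved
   into templated tail versus non-templated addition (NTA) against the
   hairpin continuation. The dedicated NTA profile uses reads ≥ 18 nt, at
   most 3 trims, and keeps miRNAs with ≥ 500 weighted reads in both
   compartments.
4. **Differential enrichment** — weighted count matrices, RPM and TMM
   normalization, a negative-binomial two-group test with
   method-of-moments + trend dispersion, Benjamini–Hochberg FDR, and
   boundary-inclusive enrichment calls at |log2 FC| ≥ 1 and FDR ≤ 0.001;
   per-direction seven-region set partitions across the three cell
   lines; Spearman and PCA sample summaries.
5. **qPCR and reporter arithmetic** — ΔΔCt fold changes
   (`FC = 2^-ΔΔCt`, replicate Cts averaged first, all Cts ≤ 30),
   dilution-series standard curves (mean Ct against log10 copies/µl),
   absolute copy estimation by curve inversion, percent-increase of
   transferred miRNA, and Luc/β-Gal reporter normalization.
6. **Motif scanning** — deterministic IUPAC scanning (e.g. GGAG, YCC)
   with an optional 3'-window restriction and a hypergeometric
   set-enrichment test. De novo motif discovery is out of scope; the
   module tests given motifs only.

## The synthetic-data generator

Sequencing data for this study design are not publicly deposited, so the
package is driven end to end by `sim_reference()` / `sim_profile()` /
`sim_reads()`, which generate a toy reference world — hairpins with 5p
and 3p mature windows embedded verbatim in a single-chromosome genome
next to tRNA/rRNA/snRNA/repeat/other loci — and libraries with a
complete per-read truth table.

Design choices and defaults:

* **Alphabet.** References are stored in DNA space and simulated inserts
  are emitted in DNA space, matching FASTQ convention; motif inputs in
  RNA space are normalized (U→T) on entry.
* **Read structure.** Insert + full adapter, truncated at a fixed
  50-cycle read length, so adapter trimming is exercised realistically.
  Qualities are constant high ("I"); the pipeline never uses them.
* **Default composition** (fractions of reads): miRNA 0.60, rRNA 0.12,
  tRNA 0.08, repeat 0.08, snRNA 0.04, other 0.03, unmappable 0.05 — a
  miRNA-dominated small-RNA library with a realistic structural-RNA and
  repeat background. Mature abundances are log-normal
  (meanlog log 100, sdlog 1), giving the strongly skewed abundance
  distribution typical of miRNA libraries.
* **3' modification model.** Trim lengths 0–10 nt with P(0) = 0.75 and a
  decaying tail; tail lengths 0–3 with P(0) = 0.70; tail nucleotide
  composition A-biased (0.5/0.2/0.15/0.15), emulating the A-tail
  dominance of cellular miRNAs; a configurable fraction of tails is
  templated (copied from the hairpin continuation).
* **Export biases.** `sim_experiment()` multiplies per-mature abundance
  by `2^bias` in exosome libraries; genotype × compartment × replicate
  libraries share one base abundance, and per-replicate seeds are
  derived from the master seed, so everything is bit-reproducible.
* **Mature uniqueness.** Mature sequences are rejection-sampled to occur
  exactly once in the genome (bounded retries, explicit failure naming
  the constraint), so read attribution is unambiguous; `shared_mature`
  deliberately copies one mature across hairpins to create exact
  multi-mappers, and repeat loci are verbatim copies of one unit.

What the generator does **not** emulate: sequencing errors (beyond an
optionally clean world — there is no error model by default), PCR
duplication, UMIs, 5'-end heterogeneity of real Drosha/Dicer processing,
reverse-strand features (off by default), and the true isomiR rate
spectrum of any particular cell line, which the source study did not
publish. Passing tests therefore demonstrate algorithmic correctness
under a controlled model, not fidelity to any real library's empirical
distributions.

## Identifiability of 3' modifications

A non-templated tail whose first bases happen to match the hairpin
continuation is mathematically indistinguishable from a shorter trim
with a templated extension: any remapping procedure absorbs the matching
bases into the mapped prefix. The truth table therefore carries both the
*intended* modification and the *expected* maximal-mapping call
(`expected_trim`, `expected_nta`, plus a `template_coincident` flag), and
recovery is measured against the latter. The same reasoning fixes the
classifier's convention: the longest mappable prefix wins, so templated
tails are only declared beyond the canonical 3' end, and a read's suffix
is (except at hairpin boundaries) pure NTA.

Two consequences bound what is classifiable: the mapped prefix may never
drop below the global 15-nt length floor, and a templated extension may
overshoot the canonical end by at most the 2-nt annotation window —
reads outside these bounds are reported unclassified rather than
guessed. The genome screen runs once before the trim iteration; whether
the original analysis re-screened the genome each round is not
documented, so this is exposed as `genome_screen` and defaults to the
single screen.

## Numerical and statistical choices

* **Adapter trimming.** Substitutions, insertions and deletions all cost
  one edit; suffix overlaps of ≥ 3 nt are considered; the admissible
  occurrence with the fewest edits wins, ties broken by leftmost start.
  Exact occurrences are resolved by vectorized string search; only
  inexact candidates use the per-read semi-global DP. Trimming is
  idempotent unless an insert itself ends in an adapter prefix, which a
  second pass legitimately removes — the oracle-equivalence test pins
  the exact semantics.
* **Alignment.** `-v`-mode semantics: no indels, ≤ 2 substitutions, all
  hits in the best stratum. Exact matching is a substring-index join
  (bit-reproducible, no heuristics); mismatch search verifies candidate
  placements per unique sequence. Genome targets are searched on both
  strands, hairpin targets forward-only.
* **Category priority.** Overlapping different-class features resolve as
  miRNA > tRNA > rRNA > snRNA > repeat > other; hairpin-contained reads
  outside every extended mature window count as other ncRNA (precursor
  fragments). Weights are assigned at alignment and carried through
  annotation unchanged.
* **TMM.** Doubly trimmed (30% on M, 5% on A) weighted mean of log2
  ratios against a reference column chosen by the upper-quartile rule,
  with inverse asymptotic-variance weights, reported normalized to
  geometric mean 1. Pairs with fewer than 10 usable genes fall back to
  pure library-size scaling with a warning. Because the precision
  weights depend on depth, TMM factors are invariant to rescaling a
  sample only up to those weights (the tests allow 0.5%); the effective
  size factors are what the robustness guarantee applies to.
* **Dispersion.** Method-of-moments `max(0, (s² − µ)/µ²)` on normalized
  counts, pooled across replicated conditions or per-condition
  maximized; a lowess trend of log dispersion on log mean floors the
  gene-wise value (`final = max(gene-wise, trend)`), deliberately
  conservative at 2–3 replicates.
* **NB test.** Sum-conditioned exact test (conditioning on the rounded
  total of normalized group sums, enumerating all splits, two-sided by
  summing probabilities ≤ the observed split's) when the total is
  ≤ 5000, Wald on log2 means with delta-method NB variance otherwise.
  Fold changes use a 0.5 pseudocount. This is behaviorally similar but
  not numerically identical to the DESeq-family implementations the
  field uses; acceptance is via calibration and power properties, not
  replication of another package's p-values.
* **Multiple testing.** Benjamini–Hochberg, the conventional choice when
  only "FDR" is stated.
* **PCA.** Log2(x + 1) transform, feature centering, SVD; each
  component's sign is fixed so its largest-magnitude loading is
  positive.
* **Percent increase.** The printed formula for the co-culture
  experiment carries misplaced parentheses and a stray exponent; it is
  implemented as the conventional relative change
  `((CP_cond − CP_base)/CP_base) × 100`, which reproduces the published
  ≈34% and ≈8% from the published copy numbers (442.58, 357.23 and
  329.48 copies). The published "approximately 114 copies" differs from
  the printed means' difference (113.1) by rounding; the difference is
  reported as computed.
* **High-confidence subset.** The real-data analysis restricts isomiR
  calling to a curated high-confidence miRNA set (544 entries in the
  miRBase release used); that count is a property of the annotation
  release, not of the algorithm, so the package exposes it as a
  reference-subset flag and synthetic bundles define their own subset.

## Problem sizes used by the tests and the acceptance script

Simulation scales were chosen to give tight binomial/parametric bounds
at desk scale: 10^4–10^5 reads for composition and recovery checks, 10^4
null genes for test calibration (3 vs 3 replicates, dispersion 0.1),
2000 genes for power at a fourfold change, and a 12-library experiment
(2 genotypes × 2 compartments × 3 replicates, 6000 reads each, 80
matures, 30 exported at log2 bias 2–3) for end-to-end sorting recall.
All randomness derives from explicit seeds.

## Known limitations

* The aligner and annotator are exact, desk-scale re-implementations;
  they are not tuned for genome-scale references.
* Fractional weighted counts are rounded when entering the exact NB
  test's conditioning; with heavy multi-mapping this loses sub-read
  precision.
* Enrichment contrasts are two-group only (compartment or genotype); no
  GLM covariates or interaction terms.
* isomiR 5' analysis is limited to the offset histogram the annotation
  window permits (±2 nt); internal editing is not modelled.
* The motif module tests candidate motifs; it deliberately does not
  rediscover motifs de novo.
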