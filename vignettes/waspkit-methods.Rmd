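---
title: "Methods: assembly curation, CpG methylation signatures and pan-genome rarefaction"
author: "waspkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: assembly curation, CpG methylation signatures and pan-genome rarefaction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(waspkit)
```

waspkit packages the downstream computations of a chromosome-level
insect genome project — the steps that usually live in one-off scripts —
as tested, seedable functions: assembly summary statistics, rule-based
contig decontamination, chromosome/scaffold renaming, per-gene CpG
observed/expected (CpG o/e) analysis with mixture-model component
selection, orthogroup sharing and pan/core-genome rarefaction, and
ultrametric tree age scaling. This vignette explains the models and
conventions behind each stage, the parameters that matter, and what the
synthetic-data generators do and do not emulate.

## Coordinate and sequence conventions

All coordinates are 1-based inclusive, the native GFF3 convention;
no half-open coordinates appear anywhere in the interface. FASTA ids
are the first whitespace token of the header (the full header is kept
as metadata), and character case is preserved exactly on read and
write, because soft-masked repeats are encoded as lowercase letters.
IUPAC ambiguity codes and N are accepted and preserved; they are
excluded from GC and CpG counting (a CG dinucleotide is counted only
when both bases are unambiguous).

## Assembly statistics

`compute_stats()` reports the standard QC bundle: total and largest
sequence length, scaffold count, N50, N count, gap count, and
soft-masked repeat fraction. N50 is the largest length L such that
sequences of length ≥ L cover at least half the assembly, computed by
the sorted-cumulative method (`nx()` generalizes to any Nx).

Two columns need explicit conventions because public assembly reports
disagree on them:

* **Gaps.** A gap is a maximal run of at least `min_gap_run`
  consecutive N/n characters. The default is 1; some archives only
  count runs of ≥ 10 as gaps, so the threshold is a parameter rather
  than a constant.
* **Repeat fraction.** The fraction of lowercase characters, i.e. the
  soft-masking convention for repeat-derived sequence. By default the
  denominator is the total character count including N; setting
  `exclude_n_from_repeat_denominator = TRUE` removes Ns from the
  denominator. Lowercase ambiguity codes count as masked (they are
  lowercase) but never as G+C.

## Contamination filtering

`classify_contigs()` implements a three-rule, single-pass filter over
the contigs of a draft assembly, using BLAST-style taxonomy
descriptions and a table of predicted genes assigned to orthogroups of
the host clade:

1. A contig with at least one taxonomy hit is kept iff any hit
   description contains any keep keyword (default `Polistes`,
   `Vespula`, `wasp`; case-insensitive substring match, with a
   whole-word option). A contig with hits and no keyword match is
   discarded immediately — it never reaches the later rules.
2. A contig with no hits is kept if it carries at least one predicted
   gene assigned to a host-clade orthogroup ("orthogroup rescue").
3. Remaining contigs are kept iff their GC fraction lies within
   `gc_sd_multiplier` (default 2) sample standard deviations of the
   mean GC of the contigs kept by rules 1–2. The band is computed once
   from the rules-1–2 keepers and never updated — the filter is
   deliberately non-iterative. Bounds are inclusive.

Choices the field leaves open, fixed here: the standard deviation is
the sample SD (n − 1 denominator); keyword matching is substring
rather than token-based because BLAST description formatting is
unreliable; a contig whose GC is undefined (no unambiguous base) that
reaches rule 3 is discarded with a warning. If rules 1–2 keep nothing
the GC band is undefined and the function stops with advice to relax
the keywords; if they keep exactly one contig, the band degenerates to
that single value (sd = 0) with a warning.

`assign_names()` renames records by size rank: the largest
`n_chromosomes` (default 25) become `Chr1..ChrN`, the remainder
`Scaffold0001...` with four-digit, size-ordered numbering. Ties are
broken by input order, so renaming is deterministic.

## CpG o/e as a methylation signature

In genomes with germline DNA methylation, methylated cytosines in CpG
context deaminate to thymine over evolutionary time, depleting CG
dinucleotides in historically methylated regions. The per-gene
observed/expected CpG ratio is therefore a fossil record of
methylation: a mode well below 1 marks a methylated gene class.

`cpg_oe()` supports two normalizations:

* `literal`: `n_CpG / (n_C × n_G)`. This is the classical dinucleotide
  formula written without a length factor; its values scale as
  1/length and are mainly useful for comparing genes of equal length.
* `length_normalized` (default): `n_CpG × L / (n_C × n_G)`, where L is
  the number of unambiguous bases. For dinucleotide-random sequence
  its expectation is 1, which makes the 0–1.5 axis of the usual
  per-gene histograms directly interpretable. This is the form used
  throughout the pipeline; the literal variant is retained behind the
  `normalization` argument.

The ratio is undefined (NA) when a gene has no C, no G, or fewer than
two unambiguous bases; undefined rows are kept in `cpg_table()` output
but flagged, and must be excluded before mixture fitting.

Genes are extracted with `extract_gene_sequences()` in `cds` mode by
default (concatenated CDS parts in genomic order, minus-strand genes
reverse-complemented); `gene_body` mode extracts the full genomic
span. CDS is the default because coding sequence avoids intronic
repeat content that dilutes the signature; both modes are first-class.

## Mixture-component selection

The number of modes in a CpG o/e distribution is estimated by fitting
univariate Gaussian mixtures for k = 1..k_max (default 5) in two
families — equal variance across components and free variance — and
selecting the fit with the best BIC. The BIC convention is the
model-based-clustering one:

    BIC = 2·logLik − p·ln(n),   selected by MAXIMUM,

with parameter count p = (k−1) + k + k for free variance and
(k−1) + k + 1 for equal variance. Ties go to the smaller k, then to
the equal-variance family. Other 1-D "model families" (e.g. covariance
orientation) are meaningless and omitted.

Numerical choices in the EM implementation:

* Initialization at the k data quantiles (midpoints (j − ½)/k), with
  `n_restarts` (default 10) jittered restarts from a seeded generator;
  each restart gets a short burn-in (≤ 50 iterations at tolerance
  1e-4) and only the best burn-in is polished to full convergence
  (tolerance 1e-6 relative change in log-likelihood, up to 500
  iterations). Everything is deterministic given `seed`.
* A variance floor of 1e-8 on the component SDs guards against
  singular components; a restart that collapses onto the floor is
  discarded and redrawn. Data with zero variance are rejected
  outright, and n ≥ 2k observations are required.
* The per-iteration log-likelihood trace is retained on the returned
  fit; EM guarantees it is non-decreasing, and the test suite asserts
  this for every fit it creates.

On a 3,000-gene trimodal distribution (modes near 0.4 / 0.9 / 1.4,
within-mode SD 0.08), this selection recovers k = 3 essentially always
and the mode locations to well under 0.05 — the regime in which a
"trimodal, with a depleted low mode" claim about a real gene set is
meaningful. On unimodal data it selects k = 1. The operating
characteristics are recomputed, not quoted, by the test suite and by
`scripts/acceptance.R`.

## Orthogroup sharing and pan/core rarefaction

The unit of analysis is the orthogroup — a set of genes descended from
a single ancestral gene — and the input is an OrthoFinder-style
species × orthogroup gene-count table (both the `GeneCount` and the
membership dialect are parsed). Presence means gene count ≥ 1; no
minimum-count threshold is applied. Genes not assigned to any
orthogroup are excluded from all sharing counts and enter only the
per-species gene-total percentages, when unassigned counts are
supplied.

`pan_core_curve()` computes, for every species-subset size k, the core
(orthogroups present in all k species) and pan (present in ≥ 1) sizes
per subset. When the number of k-subsets is at most `cap` (default
1,000) all subsets are enumerated; otherwise `cap` distinct subsets
are sampled uniformly without replacement via rejection with a
seen-set — cheap at this cap even when C(n, k) is astronomically
large, and exactly reproducible given the seed. The full per-subset
distribution is retained so the usual rarefaction scatter can be
redrawn, and `pan_closure()` reports the last-step pan growth as a
numerical closure diagnostic without making the biological claim.

## Ultrametric tree scaling

`scale_to_root_age()` converts a relative ultrametric phylogeny into
absolute time given a single root calibration: every branch is
multiplied by `root_age / current root height`, preserving topology
and all branch-length ratios exactly; clade ages are then read off as
root age minus MRCA depth. Ultrametricity is checked with a relative
tolerance (default 1e-6) because published trees carry rounding noise;
the tree is used as rooted, with no rerooting. On an ultrametric tree
the MRCA age of two tips equals half their path distance, which the
tests use as an independent check.

```{r tree-example}
tr <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
res <- scale_to_root_age(tr, 51, clades = list(inner = c("A", "B")))
res$report
```

## What the synthetic generators emulate

Each generator is a pure function of its arguments including the seed,
and emits a truth table sufficient to score the corresponding stage.

* `simulate_assembly()` draws host contigs at one GC level and
  contaminants at another (default 0.31 vs 0.46 — a 0.15 offset, far
  beyond the 2-SD GC band of the host contigs), log-normal lengths
  (default median 20 kb), Poisson N-gap runs with geometric lengths,
  and lowercase repeat tracts to a target masked fraction (default
  0.18). Host contigs carry a keyword-bearing taxonomy description
  except for a 10% miss rate; hitless host contigs carry
  orthogroup-rescue genes by default (`rescue_rate = 1`), reflecting
  that at typical insect gene densities (~1 gene / 10 kb) a genuine
  multi-kilobase contig essentially always contains a conserved gene —
  this is precisely the situation the rescue rule exists for. With
  these defaults the filter's discard decisions have an unambiguous
  truth and perfect recovery is the expected outcome; lowering
  `rescue_rate` creates hitless, unrescued host contigs whose GC noise
  makes ~5% of them fall outside their own 2-SD band, which is a
  property of the method, not a bug.
* `simulate_cpg_genes()` assigns each gene a component and a
  depletion/enrichment level d ~ Normal(mean, sd) truncated to [0, 2],
  then thins CG occurrences of an i.i.d. uniform sequence with
  retention probability d (for d < 1) or creates additional CGs at
  C-followed-by-non-G sites (for d > 1). The substituted base is drawn
  from the non-G alphabet excluding C when the next base is G, so a
  removed CG is never silently re-created; at d = 0 the residual CG
  count is essentially zero, far below 5% of the i.i.d. expectation.
  Because thinning also perturbs the C and G totals, the realized o/e
  at intermediate d is biased upward by a few percent relative to d;
  the generator's truth table records the drawn level, and tests that
  need exact targets use d = 1 (no thinning) or well-separated
  components.
* `simulate_orthogroup_table()` builds core / accessory /
  species-specific strata with Bernoulli accessory presence and
  1 + Poisson gene counts. Accessory orthogroups absent from every
  species are redrawn (a real table cannot contain them); the
  conditioning bias this puts on the closed-form expected core size,
  n_core + n_accessory·p^k, is O((1−p)^n) and negligible at the
  defaults. Note that an accessory orthogroup realized in exactly one
  species is, in the resulting table, indistinguishable from a
  species-specific one — truth-based tests of specificity use strata
  without accessory overlap.
* `simulate_ultrametric_tree()` rescales a random coalescent topology
  so all root-to-tip depths are exactly equal.

None of the generators attempt read-level realism, repeat-family
structure, codon structure, or Hi-C contact patterns; passing tests
demonstrate the correctness of the computations under the stated
statistical structure, not robustness to every artifact of real data.

## Problem sizes used in the checks

The test suite and `scripts/acceptance.R` regenerate everything at
desk scale: 200 random assemblies for the Nx/character-count oracles,
20 seeds × (50 host + 10 contaminant) contigs of ~20 kb for the
curation recovery, 200 × 10 kb i.i.d. genes for the CpG expectation,
40 seeds × n = 3,000 draws for the mixture operating characteristics,
a 10-species × 300-orthogroup table for the rarefaction checks, and 50
random trees for the scaling properties. Published statistics of the
three deposited *Vespula* assemblies (~176–179 Mb each) are recomputed
by the first acceptance test when the ENA archive is reachable;
everything else runs fully offline.

## Known limitations

* The "Gaps" and repeat-percent columns of public assembly reports are
  convention-dependent; match `min_gap_run` and the repeat denominator
  to the archive you are comparing against before reading those two
  columns across projects.
* The mixture model assumes Gaussian components on the o/e scale;
  strongly skewed modes can inflate the selected k. Inspect the
  BIC table and the fitted density overlay (`plot()` on the
  selection) rather than trusting a single integer.
* `read_gff3_genes()` keeps one transcript per gene (largest total
  CDS); alternative isoforms are not represented.
* Rarefaction subsets are sampled without replacement per subset size;
  per-subset core/pan values at the same k are correlated across
  overlapping subsets, so treat the per-k spread as descriptive, not
  as independent replicates.
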