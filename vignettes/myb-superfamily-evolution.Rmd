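---
title: "Methods: comparative genomics of the plant MYB superfamily"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative genomics of the plant MYB superfamily}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mybevol)
```

This vignette documents the models, rules, and numerical choices behind
each analysis stage, what the synthetic-data generators do and do not
emulate, and the design decisions taken where several defensible options
existed.

## Family identification and subfamily classification

MYB transcription factors carry one to four copies of a ~52-residue
DNA-binding repeat; the repeat count defines the four subfamilies
(1R-MYB through 4R-MYB, with counts of four or more collapsed into the
"4R-like" bucket). Membership is decided from Pfam `Myb_DNA-binding`
(PF00249) hits against the longest isoform of each gene:

* hits with E-value above `1e-5` are discarded (inclusive threshold:
  a hit at exactly the threshold survives);
* surviving envelopes are merged when their residue overlap exceeds
  half the shorter envelope, transitively; the merged envelope count is
  the repeat count.

The merge rule is a modelling choice: HMM searches regularly report a
single repeat as two overlapping envelopes, while genuine adjacent
repeats abut with little or no overlap. The 50%-of-shorter criterion
separates these two regimes. It is worth noting one consequence: the
repeat count is not formally monotone in the E-value threshold, because
an admitted long envelope can in principle bridge two previously
separate repeats. With domain-like envelope geometry (envelopes of
roughly one repeat length) this does not occur, and the property holds
on all generated inputs; pathological geometries would need envelopes
nearly twice the repeat length.

The canonical ~52-residue domain length is *not* used as a filter;
short envelopes passing the E-value gate still count.

## Copy-number statistics

Copy numbers are summarized per species and lineage category. The
dispersion statistic is the coefficient of variation with the sample
(n−1) standard deviation; it is undefined (reported missing) for fewer
than two values or a zero mean. Per-genome means are reported to two
decimals.

Per-orthogroup copy-number divergence between flowering and
non-flowering plants uses a two-sided Wilcoxon rank-sum test with zero
counts included — a species absent from an orthogroup contributes a
zero, which is informative for presence/absence divergence. The exact
null distribution is used when the pooled sample is at most 12 with no
ties; otherwise the normal approximation with tie and continuity
correction. P-values are Benjamini–Hochberg adjusted across all tested
orthogroups and flagged at an adjusted 0.05 by default. The direction
label compares group medians, falling back to means on median ties.

## Ka/Ks estimation

Duplicate pairs are consumed pre-aligned (codon-wise, `---` gap codons
allowed). The estimator is Nei–Gojobori (1986) counting:

* *Sites.* Each codon position contributes
  (synonymous single-nucleotide neighbours)/(non-stop neighbours)
  synonymous sites, so S + N = 3 per codon; sites are averaged over the
  two sequences.
* *Differences.* For each codon pair, all orderings of the differing
  positions are enumerated as single-step mutational pathways; pathways
  passing through a stop codon are excluded, the rest are averaged with
  equal weights. The rare codon pairs whose pathways all hit stops are
  skipped and counted in `n_skipped`.
* *Correction.* Proportions `pN = Nd/N`, `pS = Sd/S` are corrected for
  multiple hits with Jukes–Cantor, `d = -(3/4) log(1 - 4p/3)`;
  a proportion at or above 3/4 leaves that rate undefined.

`omega = Ka/Ks` is undefined when Ks is zero or missing; the selection
call is positive/neutral/negative as omega is above/equal to/below 1.
All per-codon quantities are precomputed as 64×64 lookup tables on
first use, so a 3,000-codon pair costs a handful of vectorized lookups.

A counting estimator was chosen over maximum-likelihood alternatives
because every intermediate quantity is exactly enumerable, which lets
the test suite verify the implementation against an independent
brute-force oracle over all 61×61 sense-codon pairs.

Ks landscapes retain pairs with Ks below 3 per species. Two deeply
diverged green algae are treated as exceptions whose retained set is
the complement (Ks above 3): all their paralog pairs predate the
cutoff, and the standard filter would discard the entire species. The
histogram uses 0.05-wide Ks bins.

Pair selection from orthogroups is interpreted as *all unordered
within-species pairs per orthogroup*; the upstream synteny step that
would restrict this further is out of scope and consumed via the pair
table.

## Duplicate expression fates

Expression is quantified as RPKM,
`count * 1e9 / (gene_length * total_mapped_reads)`, and a gene counts
as expressed only when RPKM strictly exceeds 5.

The per-tissue test statistic for a pair (a, b) is the mean per-library
`log2((RPKM_a + 1)/(RPKM_b + 1))` over the tissue's replicates. The
pseudo-count of 1 stabilizes ratios for weakly expressed genes. A
verdict (`a_higher`/`b_higher`) requires a BH-adjusted p-value below
0.05 *and* a mean absolute log2 ratio of at least `log2(2)`; with a
single replicate only the fold-change gate applies. BH adjustment runs
across every (pair, tissue) test in the run.

With two or three replicates a per-test variance estimate has one or
two degrees of freedom, and no real 8-fold effect can reach an adjusted
5% FDR through a plain t-test: the p-value of a df-2 t-test at
noncentrality ~8 behaves like `W/64` with `W` standard-exponential, and
the BH step-up over a run with mostly null tests then rejects almost
nothing. Count-based DE tools avoid this by sharing dispersion
information across genes. The same cure is applied here: replicate
variances are moderated across all tests with an empirical-Bayes prior
(`limma::squeezeVar`), and the moderated t statistic is referred to the
inflated degrees of freedom. `moderated = FALSE` restores the plain
t-test for comparison.

Fate classification from the per-tissue verdicts, SNFD checked first:

* **SNFD** — each gene significantly higher in at least one tissue;
* **AED** — one gene higher in at least ⌈T/3⌉ of T tissues (ceiling,
  the conservative reading of "at least 1/3 of tissues") and the sister
  never significantly higher;
* **NDD** — everything else.

Pairs in which neither gene exceeds RPKM 5 in any library are excluded
from classification (reported with a missing fate): a fate statement
about two silent genes would be meaningless. The cross-species
conservation matrix marks, per species × orthogroup, whether any
within-orthogroup pair of that species is SNFD, the species is present
without an SNFD pair, or absent.

## HGT screening

Orthogroups containing both plant and fungus/oomycete members are
candidate horizontal-transfer groups. The per-tree screen formalizes
what a curator would do by eye as a *double-enclosure* rule: a maximal
same-kingdom clade C is called when its sister clade and the next-outer
neighbouring clade are both entirely the other kingdom and both
enclosing bipartitions carry bootstrap support of at least 70. The
direction runs from the surrounding kingdom into C's kingdom. Two
guards keep the rule honest:

* only minority clades are callable (at most 20% of the tips), so the
  vertically inherited majority is never reported as transferred;
* clades meeting only the sister condition are reported separately as
  low-confidence candidates rather than calls.

Trees are unrooted and midpoint-rooted before analysis (support values
carried as bipartition attributes), which makes the screen invariant to
the input rooting and to tip rotations — properties the test suite
checks explicitly. Ranked homology hits provide independent
corroboration: a candidate is corroborated when more than half of its
top ten hits come from the donor kingdom.

## TE context and LTR dating

The occurrence rate of TEs (ORT) in a region is the length of the union
of TE intervals intersected with the region, divided by the region
length; overlapping annotations are merged before measuring, so ORT is
bounded by 1 and monotone in the annotation set. Regions are gene
bodies and strand-aware 5-kb flanks, truncated (not shifted) at contig
ends; a fully truncated flank has no length, its ORT is reported
missing, and it is excluded from correlations. Flank overlap with
neighbouring genes is not excluded.

Intact LTR elements are dated from the divergence of their two terminal
repeats, `T = (1 - identity)/(2 mu)` with `mu = 1e-8` substitutions per
site per year by default, reported in million years. Identity is
consumed from the annotation (`ltr_identity=`), never recomputed from
sequence. ORT–expression association uses squared Pearson correlation
per fate class over genes passing the RPKM > 5 filter, with at least
three genes and nonzero variance in both variables.

## Synthetic data: what it does and does not emulate

Each generator writes the exact input format of its stage plus a
ground-truth table, is deterministic given its seed, and uses its own
seeded stream so adding one generator never perturbs another. Defaults
are the study conditions used by the acceptance checks:

* *Domain hits* — planted repeat counts 0–4 as ~52-residue envelopes
  with 10-residue linkers; decoys fail the E-value gate; occasional
  near-duplicate envelopes exercise the merge rule. The planted counts
  are recoverable exactly.
* *Codon pairs* — a uniform-sense-codon ancestor evolved by uniform
  single-nucleotide proposals accepted at relative rates 1 : omega
  (synonymous : nonsynonymous), with stops rejected; `t = 0.3` expected
  synonymous substitutions per synonymous site by default — deep enough
  divergence to require the multiple-hit correction, shallow enough
  that counting methods remain reliable. The proposal budget is
  `3 t / p_syn-accept` proposals per codon, which makes the realized
  synonymous rate per synonymous site approximately `t`. Because the
  mutation mechanism is exactly the one the estimator assumes,
  recovery tests isolate estimator correctness, not model mismatch.
* *Expression* — negative-binomial counts (dispersion 0.1) at a
  log-normal per-pair baseline RPKM (median 50); SNFD pairs get
  reciprocal 8-fold effects in one tissue each, AED pairs one-sided
  8-fold effects in ⌈T/3⌉ tissues, NDD pairs none. Default fate mix
  SNFD 0.25 / AED 0.45 / NDD 0.30, reflecting the empirical dominance
  of asymmetric expression among duplicates. Six tissues × three
  replicates.
* *Gene trees* — two reciprocally monophyletic random clades; each
  planted transfer grafts a tip of one kingdom onto a pendant branch
  inside the other kingdom's clade; one global support value per tree.
* *TE annotations* — insertion times drawn around requested peaks
  (relative spread 0.15), converted to terminal-repeat identities by
  inverting the dating formula; optional region layouts plant exact
  ORT values.

What the generators deliberately do **not** emulate: read-level
RNA-seq (counts are drawn directly), alignment and annotation error,
correlated expression between tissues, rate heterogeneity and
transition/transversion bias in codon evolution, gene-tree estimation
error (support is planted, not inferred), and nested or fragmented TE
annotations. Passing recovery tests therefore demonstrates that each
algorithm does what it claims under its own model assumptions — not
that those assumptions hold for any particular real genome.

## Numerical choices and degenerate inputs

* Isoform-length ties break to the lexicographically smaller
  transcript id; coordinates are 0-based half-open internally,
  converted once on ingest.
* A fully tied Wilcoxon sample (zero rank variance) returns p = 1.
* Jukes–Cantor leaves a rate undefined at `p >= 3/4`; omega is
  undefined at Ks = 0; both propagate as missing, never as zero.
* Fates need verdicts from at least two tissues; fewer leaves the fate
  unassigned with a warning.
* Empty regions yield missing ORT (never 0); empty hit tables are
  uncorroborated, not errors.
* BH-adjusted p-values are computed once per run over all tests, so
  adding pairs to a run can change individual verdicts — by design,
  matching how FDR control is meant to be applied.

## Problem sizes

The bundled checks run at desk scale, chosen so the full suite
completes in a few minutes on one core: fate recovery uses 300 pairs ×
20 seeds; omega recovery 3,000-codon pairs × 50 seeds per planted
value; the HGT screen 100 transfer-free and 40 planted trees of 20–50
tips; oracle comparisons cover all 3,721 sense-codon pairs and dozens
of random interval/rank-sum instances. Dataset-scale quantities from
hundreds of genomes (total family counts, genome-wide TE abundances,
dataset-level R² values) are outside what synthetic desk-scale runs can
reproduce and are not asserted anywhere.

## Known limitations

* NG86 with equal-weight pathway averaging slightly underestimates
  omega above 1 (about −10% at omega = 2 under the bundled simulator)
  and assigns small nonzero Ka to some synonymous-only multi-step
  changes; both are inherent to the counting method.
* The double-enclosure HGT rule requires an intact local topology;
  transfers sitting exactly at the recipient clade's root, or adjacent
  to a second transfer, can evade it. Support values are taken at face
  value.
* The moderated variance prior assumes log-ratio variances are
  exchangeable across pairs and tissues; strongly heteroskedastic
  designs would warrant per-stratum moderation.
* Orthogroup-derived duplicate pairs conflate tandem and WGD
  duplicates; no synteny information is used.
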