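---
title: "Codon-level germline-somatic co-occurrence: models and methods"
author: "codoncooc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Codon-level germline-somatic co-occurrence: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(codoncooc)
```

## The problem

Somatic variant callers treat the matched normal genome as a subtraction
baseline. When a tumor-acquired SNV lands in the same codon as an inherited
germline SNP on the same haplotype, the substitution actually translated in
the tumor is the *joint* product of both alleles, but the caller annotates
the somatic allele against the reference codon alone. Because multiple
changes to a codon are more likely to cross polarity classes or create a
stop, the reported substitution systematically understates the impact of the
true one. `codoncooc` detects these codon-level co-occurrences, phases them
from tumor read evidence, re-annotates the substitution the tumor actually
carries, quantifies the impact shift, and provides the null models needed to
ask whether such events are under selection.

## Detection and phasing

A **candidate** is any (germline, somatic) SNV pair within 2 nucleotides of
each other whose positions fall in the same codon of at least one shared
transcript. The 2-nt window is the natural same-codon reach for contiguous
codons; a codon split across a splice junction can place two same-codon
positions farther apart, and such pairs are deliberately *not* flagged (the
window, not the codon, defines the search). Pairs sharing a codon are merged
into a single event per codon, so one somatic plus two germline variants is
one event; a codon annotated in several transcripts yields a single event
with every affected transcript recorded. Codons whose reference translation
is a stop are never eventized: the enumeration universe is the 61 sense
codons. A germline and a somatic call at the identical genomic position
would be an allele replacement, not a co-occurrence, and is excluded.

**Phasing.** An evidence unit is a read or read pair (both mates share a
read id and count once; a unit covers a position if either mate aligns over
it without a deletion). Bases below quality 20 (configurable `minBaseq`) are
ignored. A unit is *cis-supporting* if it covers every variant position and
carries every alternate allele; *trans-supporting* if it covers every
position, carries every somatic alternate, and the germline *reference*
base at one or more germline positions. The verdict is cis when
cis-supporting units reach `minSupport` (default 2 — the conservative
reading of "supported by multiple reads") and outnumber trans-supporting
units; symmetrically for trans; everything else, including exact ties and
uncovered events, is ambiguous. These thresholds replace the manual
inspection of alignments that a human reviewer would perform, and the
majority rule is our stand-in for how a reviewer would resolve conflicting
support.

## Re-annotation

The **reported** substitution applies the somatic alternate alleles to the
reference codon — what a conventional pipeline annotates. The **true**
substitution applies germline then somatic alternates (disjoint positions,
so order is immaterial) when the event is in cis; in trans the alleles sit
on different haplotypes and the true substitution equals the reported one.
The reference residue of the true substitution is deliberately the
*reference-genome* residue, not the germline-SNP residue, so a
germline-silent plus somatic event can legitimately read `V2V -> V2D`.
Changes are classified by crossing the two categories, with
missense-to-missense split into `no_change` (same alternate residue) versus
`missense_to_missense`. Residue numbering always follows each transcript's
own CDS numbering; the package never renumbers a residue across isoforms
within one event, and `classifyChange(strict = FALSE)` exists solely to
classify printed tables whose two columns use different isoform numbering.

**Coordinates and strand.** Externally everything is 1-based inclusive (VCF,
GFF, the BED dialect converts from 0-based at the reader). Internally,
codon positions and codons are expressed in coding orientation. Genomic
alleles are complemented into coding orientation at the point where a
variant meets a specific transcript, not in the VCF reader: a single variant
can hit transcripts on both strands, so the reader cannot know the target
orientation. Transcripts whose CDS length is not divisible by 3 or whose
sequence carries ambiguity codes are skipped with a warning, never patched.

## Impact scale

Scores live on a 0–100 scale with two fixed anchors: silent substitutions
score 0 and stopgains score 100, in every mode. Missense substitutions are
scored either from an external per-substitution table (gene + compact
notation, e.g. `T316I`) or by a built-in surrogate: Grantham's (1974)
physicochemical distance, computed from side-chain composition, polarity and
volume (weights 1.833, 0.1018, 0.000399; scaled so the 190 pairs average
100), then min-max rescaled onto (0, 100] so the mildest exchange (Leu/Ile)
scores just above 0 and the most radical (Cys/Trp) scores 100. The surrogate
preserves exactly the properties the downstream analyses rely on —
boundedness, the silent/stopgain anchors, and monotonicity in radicality —
and nothing else; it is not a substitute for a trained impact predictor,
which is why an external score table can be dropped in. When a variant
affects several isoforms the per-isoform scores are averaged (arithmetic
mean; maximum available as an option — the two give highly similar
downstream results).

## Enumeration over the 61 sense codons

For each sense codon and each number of changed positions n ∈ {1, 2, 3},
every distinct outcome (choose the positions, 3 alternate bases each: 9, 27
and 27 outcomes) is translated and marked nonconservative if it is a stop
or crosses the polarity classes polar {G,S,T,C,Y,N,Q}, nonpolar
{A,V,L,I,P,F,W,M}, acidic {D,E}, basic {K,R,H}. Outcomes are unweighted
counts — no mutation-spectrum weighting — because the question is
combinatorial: what *could* a second hit do. The column averages rise with
n, which is the quantitative form of the motivation above.

## Null models and tests

All p-values are reported raw (no multiple-testing correction) and every
stochastic routine takes an explicit seed.

**Genotype-composition cis:trans expectation.** A homozygous germline SNP is
on both haplotypes, so any somatic co-hit is in cis; a heterozygous SNP is
in cis half the time. With hom/het counts (h, e) the expected cis fraction
is (h + e/2)/(h + e). The observed cis/trans split of candidates is compared
by a two-sided Fisher exact test against this expectation. The expected
column must be materialized as counts; by default it is materialized at the
observed total, but the expectation is actually derived from the genotype
composition of *all* germline variants in the cohort — a far larger
population — and passing that scale via `expectedN` makes the test approach
a calibrated exact binomial test. The package exposes both because the
first is the more literal 2×2 reading and the second is the one that is
calibrated under the neutral model (we verified type-I error ≈ 0.042–0.045
at α = 0.05); the calibration tests use the cohort-scale form. Expected
counts are rounded half-up, fixed and documented.

**Codon-position pair expectation.** Under "germline variants follow the
cohort's codon-position frequencies, somatic variants have no codon
preference", the ordered pair (g, s) has probability f_g × 1/2 over the two
non-germline positions (same-position events are excluded, so the support is
the six ordered pairs with g ≠ s; the renormalization is a no-op when f sums
to 1). A chi-square goodness-of-fit against this conditioned expectation,
and against the naive uniform (1/3) expectation, reproduces the two-stage
result: apparent third-position bias under the naive model, none after
conditioning on where germline SNPs actually sit.

**MAF resampling null.** The mean population MAF of event-involved germline
SNPs is compared to the distribution of means of same-sized sets drawn
without replacement from a population MAF pool (default 1000 draws); the
z-score against that null and an empirical two-sided p are reported. A pool
equal in size to the observed set (or constant) is a degenerate-pool error.

**Representation and proportion tests.** Event amino-acid proportions are
correlated (Pearson) with background proportions, and each amino acid gets a
one-sample proportion z-test *without* continuity correction — the
corrected version is conservative enough to fail its own type-I calibration.

**Remaining tests.** Burden-event association uses Spearman rank correlation
(average ranks under ties), overall and per cancer type. Census-gene
enrichment is an upper-tail hypergeometric probability on distinct genes.
The paired impact shift uses the two-sided Wilcoxon matched-pairs
signed-rank test (zeros dropped by default; Pratt zero-ranking available via
a normal approximation) plus the mean relative increase over pairs with a
positive reported score. VAF comparisons use Welch's two-sided t-test —
"independent t test" underdetermines the variance assumption and unequal
variances is the safer default; two constant equal groups return p = 1 by
convention (and p = 0 when constant but different).

## The simulator's stated world

`simulationConfig()` encodes one fixed world, chosen once:

* **Toy exome** — 20 transcripts × 120 codons on one contig, alternating
  strands (so coding-orientation handling is always exercised), sense codons
  plus a terminal stop, 50-nt intergenic gaps.
* **Population SNPs** — density 0.02 per coding site; MAF ~ Beta(2, 2.08),
  mean 0.49, matching the observed common-SNP character of co-occurring
  germline variants; third-codon-position weight 3 (i.e. 60% of SNPs in the
  third position), a deliberately strong form of the third-position bias.
* **Genotypes** — Hardy–Weinberg from the site MAF; a `het_only` mode makes
  every carrier heterozygous for phase-model calibration.
* **Somatic mutations** — per-patient burden Poisson(30) by default, with
  desk-scale cancer-type presets (BRCA 10 … SKCM 100) that encode only
  burden and a single pyrimidine-bias knob (`ctBias`, the probability of
  drawing from the C>T/G>A channel); no attempt at full signatures.
* **VAF** — Beta(6, 14): unimodal, mean 0.3, the clonal-heterogeneity peak.
* **Phase model** — a somatic variant near a heterozygous germline site
  lands on the SNP haplotype with probability `cisProb` (0.5 = neutral);
  homozygous sites are cis by construction.
* **Reads** — fixed windows around every somatic variant with a germline
  neighbour, alternating haplotypes across reads (balanced allele
  coverage), constant quality 30, configurable error rate. The somatic
  allele is clonal on its haplotype in the *read* model; the VAF model
  lives in the emitted VCF. This is the simplest model that exercises
  phasing; it does not emulate sampling noise in allele fractions.

Ground truth is built by running the package's own candidate definition
against the haplotype bookkeeping, so truth and pipeline agree on what an
event *is*, and disagreement can only come from the read-evidence stage —
exactly the stage being tested. Note one consequence of merging: an event
with two heterozygous germline variants (or two somatic variants) is in cis
only if a single haplotype carries *all* alternate alleles, so the cis
fraction of compound events is below `cisProb`; calibration checks therefore
condition on single-pair events.

What a green test establishes: the machinery — mapping, merging, phasing,
re-annotation, accounting — is exact on error-free, balanced, clonal reads,
and the statistics are calibrated under the generative null. What it does
not establish: performance under alignment artifacts, strand bias, subclonal
structure, or capture unevenness, none of which the simulator attempts.

The package also ships `syntheticS1Table()`, an explicitly **synthetic**
stand-in for a per-event supplementary table that is not redistributable:
392 events whose cohort-level marginals match the published summary values
(56.4% changed annotations, six three-base events, 53% homozygous germline
split), with every substitution pair realized from the genetic code. It
exists to validate the cohort summarizers; it is not the original data, and
no conclusion about the original cohort follows from it.

## Numerical choices and degenerate inputs

Half-up rounding for expected Fisher counts; exact cis/trans ties are
ambiguous, never broken by heuristics; `mapGenomicToCodon()` returns `NULL`
(not an error) outside the CDS, which callers treat as "no event"; empty
VCFs, empty candidate lists and zero-patient cohorts flow through with empty
outputs, while malformed inputs (missing contigs, unparseable substitutions,
out-of-domain expectations) are hard errors. Multi-allelic VCF records are
decomposed per alternate allele; indels are counted and skipped (the model
is SNV-only throughout). VAF precedence is fixed as tumor-sample `AF`, then
`AD`-derived alt/(ref+alt), then missing, and the chosen source is recorded.

## Limitations

Spliced same-codon pairs farther than 2 nt apart are not searched;
statistical (population-LD) phasing is out of scope, as is somatic-somatic
co-discovery as a headline output; the surrogate impact scale is ordinal,
not biological; and the simulator's read model is intentionally minimal. The
transcript set used for codon frames is whatever annotation the user
supplies; outputs record their inputs in provenance headers rather than
assuming any particular gene model.
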