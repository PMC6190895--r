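---
title: "Trio-based de novo variant analysis with trioDNV"
author: "trioDNV authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trio-based de novo variant analysis with trioDNV}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trioDNV)
```

# Overview

trioDNV asks a narrow question rigorously: given whole-genome variant calls
for a family trio (sire, dam, offspring) from two independent callers, which
variants in the offspring are genuine germline *de novo* mutations, how many
new mutations per base pair per generation does that imply, and do those
mutations cluster near CRISPR/Cas9 off-target sites or look like ordinary
spontaneous mutagenesis?

The package implements five connected components:

1. a **seven-stage filter cascade** that reduces millions of raw calls to a
   handful of de novo candidates, with a per-stage count trace;
2. a **mutation-rate estimator** built on an effective (callable) genome
   size derived from coverage windows;
3. a **nine-class substitution-spectrum** summary;
4. a **PAM-aware off-target search** with a distance-to-site null model and
   Kolmogorov–Smirnov comparison;
5. **kinship-based pedigree validation**.

A synthetic-trio simulator with complete ground truth makes every stage
testable without any sequencing data.

# The filter cascade

A de novo mutation appears heterozygous in the offspring and in neither
parent. Almost everything that *looks* like that in raw call sets is an
artifact: caller disagreement, shared polymorphism, coverage fluctuation,
mis-genotyped parents, or misalignment. The cascade removes these causes one
criterion at a time, in the published filtering-table order:

| stage | keeps a variant when |
|---|---|
| intersection | both callers report the same normalized (chrom, pos, ref, alt) key |
| cohort uniqueness | the alternate allele is carried by the focal offspring and by **no** other cohort member (parents included) |
| known database | the key is absent from the population variant database |
| depth / allelic balance | each parent has depth ≥ 12 and the offspring depth is ≥ 1/10 of the summed parental depth |
| PL pattern | offspring PL(AA, AB, BB) = (> 20, 0, > 0) and each parent = (0, > 20, > 20) |
| soft clip | the offspring's mean soft-clipped read fraction is ≤ 10 % |
| review | context flags (homopolymer, clustering, nearby N) are *reported*, not removed, by default |

All thresholds live in `filterCriteria()`. Three boundary conventions
matter and are deliberate:

* Removal conditions are the strict inequalities as published ("< 12",
  "< 1/10", "> 10 %"), so equality always passes: parental depth exactly 12
  is kept, offspring depth exactly one tenth of the parental sum is kept,
  a soft-clip fraction of exactly 0.10 is kept.
* The depth fraction is compared in integer arithmetic
  (`10 × offspring ≥ sire + dam`) so no floating-point boundary artifacts
  are possible.
* The PL pattern assignment (offspring het-supporting, parents confidently
  hom-ref) is the only reading of the published criterion consistent with a
  heterozygous de novo call; the published wording swaps the two patterns
  between two clauses and is self-contradictory as printed.

Stages 2–6 are per-variant predicates, so their order cannot change the
final candidate set — only the trace differs. The test suite asserts this by
permuting the stages.

The stage after soft-clip filtering defines `mu_alpha`, the candidate count
fed to the rate estimator. The review stage only annotates by default
because "manual examination" is not an algorithm; a strict mode
(`strict_review = TRUE`) removes flagged candidates for users who want a
fully automated proxy. Review flag defaults — homopolymer run ≥ 8 bp,
another candidate within 100 bp, an N base within 20 bp — are heuristics
chosen to mirror what a human reviewer looks for in a genome browser;
they are configurable and carry no claim of matching any particular manual
review.

Missing data policy: a variant with a missing genotype, depth or PL in a
*trio role* is excluded at the first stage that inspects that field, and the
exclusion is counted in that stage's trace entry, so traces stay
interpretable. A missing soft-clip fraction passes with a warning (the SCF
field is optional in the VCF contract); a missing genotype in a non-focal
cohort member counts as non-carrying.

# Effective genome size and the mutation rate

Mutation-rate denominators must count only base pairs where a de novo call
*could* have been made. The package follows the coverage-window recipe: tile
the autosomes with fixed 10-kb windows, average depth per window, and keep
windows whose mean depth lies in the callable range 13×–130× (both ends
inclusive; the bounds are absolute depths, not multiples of the mean). The
effective size is then exactly

$$R = n_\text{windows} \times \text{window size},$$

and the per-base-pair per-generation rate for one offspring with
`mu_alpha` candidates is

$$\hat\mu_g = \frac{\hat\mu_\alpha}{2R},$$

the 2 accounting for diploidy.

```{r rate}
eg <- 2457220000            # 245,722 windows of 10 kb
mutationRate(53, eg)[, c("mu_alpha", "R", "mu_g_1e8_rounded")]
```

Which cascade count feeds `mu_alpha` is a genuine design choice: the
published table reports both a post-PL/soft-clip count and a smaller
post-manual-check count. Back-calculation against the printed per-animal
rates identifies the post-soft-clip (stage-6) count as the one used
(53/(2 × 2,457,220,000) = 1.08 × 10⁻⁸ reproduces the printed value; the
post-manual count does not), so `runCascade()` exports that count as
`mu_alpha` while both remain available. Rates are reported raw and in 10⁻⁸
units rounded half-up at two decimals, matching table presentation; full
precision is retained internally.

# Substitution spectrum

Spectrum reporting uses the nine-class scheme
T>G, T>C, T>A, G>T, G>A, C>T, A>T, A>G, A>C. Twelve ordered substitution
types map onto nine labels; of the three types not listed, C>A folds onto
its reverse complement G>T, while the complementary pair C>G/G>C has no
listed representative, so both fold onto a configurable target (default
G>A, the listed class sharing the G reference base; `cg_target` exposes the
choice). The fold affects only labels, never rates or filtering.

`compareSpectra()` applies the paired two-sided Student's t-test across the
nine per-class proportion pairs, as the source analysis names. A caveat
worth stating plainly: when both profiles are complete compositions their
paired differences sum to zero by construction, so the mean difference is
identically zero, the statistic collapses to ~0 and p to ~1. The test can
flag bookkeeping mismatches but has essentially no power against spectrum
shape differences; the package returns the degenerate result (statistic 0,
p 1) explicitly when every difference is zero. A contingency-style test on
counts would be the more powerful choice but is outside the reported
procedure.

# Off-target search and the distance null model

`predictOfftargets()` scans both strands of the genome for 20-nt windows
followed (3′, in strand orientation) by a PAM matching an IUPAC pattern
(`NGG` by default, `NRG` for the relaxed preset), with Hamming mismatches
within a total budget and a tighter budget inside the PAM-proximal *seed*
region. Defaults: 5 total mismatches, 12-bp seed with at most 1 seed
mismatch — the seed length follows the common off-target-scanner convention
since no seed length is published; the (≤ 1 seed, ≤ 4 non-seed)
parameterization is the default for distance analysis, and (`NRG`, ≤ 3
total) is the named stricter preset for variant-overlap screening. `N`
bases never match, neither against the protospacer nor under a PAM `N`.
The implementation is an exact vectorized scan — no heuristic index — and
the test suite proves it equal to an independent per-window oracle on
hundreds of randomized genomes.

Two-predictor consensus (the published workflow intersects two external
prediction tools) is emulated by intersecting two parameterizations of this
single engine on (chrom, start, strand, guide); externally produced BED
site lists can be matched the same way.

The null model asks: are de novo variants closer to off-target sites than
random variant positions are? Distances are measured from a variant
position to the nearest site interval as the gap size (0 inside or
immediately adjacent; the BED/IRanges convention — a position 121 bp before
a site's first base is 120 bp away). The null pool defaults to all
cohort-called SNV positions, sampled with replacement (100,000 draws by
default, seeded); a uniform-over-genome pool is equally easy to supply
since the published description is ambiguous between the two. The observed
and null distance distributions are compared with the two-sample two-sided
KS test using the asymptotic p-value (distances are integers, so exact
small-sample p-values are unavailable under ties), and
`distanceCIBand()` provides a percentile-bootstrap band of the null CDF
(the published figure's 95 % band is equally consistent with an analytic
binomial band; bootstrap was chosen for its freedom from per-quantile
independence assumptions and is seed-reproducible).

# Kinship validation

Pedigree errors would silently inflate "de novo" counts, so declared trios
are checked against genotype-derived kinship before any filtering. The
estimator is the within-pair robust heterozygosity-concordance form (the
KING-robust family):

$$\hat\varphi_{ij} = \frac{N_{Aa,Aa} - 2\,N_{AA,aa}}{N_{Aa}^{(i)} + N_{Aa}^{(j)}}$$

over sites genotyped in both individuals. It needs no allele-frequency
estimates, is invariant to allele-label flips, and is computable in one
pass — the reasons it was chosen over frequency-weighted estimators, since
the source analysis names no estimator. Expected values: 0.5 for
self/duplicates, 0.25 for parent–offspring, 0.125 for half-sibs, 0 for
unrelated. `validateTrio()` passes a trio when both parent–offspring
coefficients fall in the standard first-degree window [0.177, 0.354]; the
sire–dam pair is checked but warns rather than fails by default, because
breeding designs (including the one that motivated this pipeline) may
legitimately mate related animals.

# The synthetic-trio generator

`simulationConfig()` / `simulateGenome()` / `simulateTrioCallsets()` /
`simulateCoverageWindows()` generate a complete, seeded input set with
ground truth:

* **Genome** — uniform-composition random chromosomes (default two 120-kb
  autosomes plus a 60-kb X) with, per guide, an exact protospacer+PAM
  on-target and planted off-target copies at configured (total, seed)
  mismatch counts, on random strands, without overlap.
* **Population variation** — SNPs at rate 2 × 10⁻³ per bp with
  Hardy–Weinberg founder genotypes and Mendelian transmission to the
  offspring; 95 % of them are present in the known database, emulating
  database-shared polymorphism plus a novel remainder.
* **De novo events** — heterozygous in the offspring only, absent from
  parents, cohort and database. They are planted at *callable* sites: trio
  depths are clamped into the callable range, offspring het alt-reads are
  conditioned away from the extremes, and non-carrying trio members read
  error-free at those sites. The planted set therefore emulates the
  discoverable de novo set, which is what the recall-1.0 recovery property
  and the exact rate identity $\hat\mu_g = n/(2R)$ require; detection
  sensitivity of real pipelines to marginally covered events is explicitly
  *not* modeled.
* **Depth and PL** — negative-binomial depths around a 36.8× mean
  (dispersion 0.15), matching the study's sequencing scale, and PL triples
  as phred-scaled binomial genotype likelihoods of the simulated ref/alt
  read counts, min-normalized and capped at 255.
* **Artifacts** — injected one criterion at a time (orthogonal design):
  a low-depth parent, an allelic-imbalance offspring, an inconsistent
  parental PL triple, a high soft-clip fraction, a database-shared key, a
  cohort-shared carrier. Each class is removed at exactly its designed
  stage, which is what makes stage-level attribution testable. Counts are
  integers per class rather than rates, so attribution is exact.
* **Caller discordance** — caller B independently drops each variant with
  the configured probability.
* **Coverage windows** — a configured fraction of windows is forced outside
  the callable range (half below, half above), the rest drawn inside it.

All draws derive from one `rng_seed` (genome, call sets and windows use
fixed offsets from it), so identical configurations produce byte-identical
files. What the generator does **not** emulate: linkage disequilibrium,
recombination, read-level errors/FASTQ, indel-rich repeat expansions, or
sequencing-batch structure. Passing tests therefore demonstrate the
*logic* of the cascade and estimators, not the field performance of any
caller.

# Numerical and scale choices

* Positions are 1-based internally and in VCF; BED export converts to
  0-based half-open. Conversion happens only in readers/writers.
* Indels are left-aligned and parsimony-trimmed against the reference
  before any comparison; normalization is idempotent and collapses all
  spellings of the same event in a tandem repeat onto one key. The 2–100 bp
  indel size gate is enforced when records are constructed.
* Multiallelic VCF rows are split into biallelic records; the PL triple of
  each split record is taken from the standard genotype-index subset of the
  full PL vector.
* Effective sizes, rates and window counts are exact integer/double
  arithmetic; `R` can exceed 32-bit range and is held as a double.
* Test problem sizes — 120-kb chromosomes, ~600 population SNPs per cohort,
  50-kb off-target genomes, 500 KS replicates at 200-vs-2000 subsamples,
  10,000 kinship sites — were chosen as the smallest scales at which every
  property is statistically decisive; the KS subsample sizes sit where the
  asymptotic two-sample p-value is close to nominal (smaller observed
  samples make it visibly conservative).

# Known limitations

* The review stage is a proxy; nothing replaces looking at alignments for
  the final shortlist.
* The paired t-test on complete spectra is near-degenerate (see above).
* The off-target scanner is an exact linear scan: right for genomes up to
  tens of megabases and for tests; genome-scale production scans would want
  an indexed engine with the same contract.
* Kinship windows assume an outbred, homogeneous cohort; inbreeding shifts
  parent–offspring coefficients upward and the first-degree window may need
  widening in such designs.
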