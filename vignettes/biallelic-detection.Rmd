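---
title: "Detecting biallelic transcript expression without genotypes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting biallelic transcript expression without genotypes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(biallele)
```

## The inference problem

A gene expected to be monoallelically expressed — a male X-linked gene, or a
pseudoautosomal-region gene whose Y-linked copy is epigenetically silenced —
should show a single base at every transcribed position. If the silenced
copy is reactivated, positions where the two alleles diverge become visibly
heterozygous in RNA-seq: the fraction of reads matching the reference base
drops from ~1 toward ~0.5. When genotypes are unavailable, that reference
fraction is the only evidence, and the question becomes a per-position
classification problem: are these base counts consistent with homozygous
(monoallelic) expression, with balanced heterozygous expression, or with
neither?

`biallele` treats one pileup column — the A/C/G/T read counts at one
transcript coordinate in one sample — as the observation unit. All
coordinates are 1-based and inclusive throughout.

## The genotype model

Let $k$ be the reference-base count out of used depth $d$ (non-reference
bases are pooled; the used depth is the A+C+G+T total after excluding
deletions and ambiguous bases). Under per-base miscall probability
$\epsilon$, substituting uniformly among the three other bases, the
probability that a read matches the reference is

$$p_{RR} = 1-\epsilon, \qquad
  p_{RA} = \tfrac12 (1-\epsilon) + \tfrac12\,\epsilon/3, \qquad
  p_{AA} = \epsilon/3$$

for homozygous-reference, heterozygous and homozygous-alternative
expression. At $\epsilon = 0$ these reduce to the idealised values 1, 0.5
and 0: a heterozygous SNP position matches the reference with probability
0.5, a homozygous one with probability 0 or 1. Each class is scored with a
binomial log-likelihood $\log \mathrm{Binom}(k; d, p_g)$, combined with
priors $\pi_g$ (uniform by default — nothing in the design argues for an
informative prior, and the priors are exposed) and normalised into
posteriors.

Numerical choices:

* all likelihood arithmetic is in log space with max-subtraction before
  exponentiating, so posteriors are stable at $d$ in the thousands;
* a call is refused (`no_call`) unless $d \ge d_{\min}$ and the winning
  posterior reaches $\tau$; ties in the posterior (possible only in
  degenerate configurations) resolve to the first class in the order
  hom-ref, het, hom-alt;
* $d = 0$ columns carry the prior as posterior and are always `no_call`;
* $\epsilon \ge 0.75$ is rejected everywhere: at that point
  $p_{RR} \le p_{RA}$ and the classes are no longer ordered.

The defaults $d_{\min} = 20$ and $\tau = 0.95$ are chosen so that a handful
of miscalls at typical depths cannot fabricate a heterozygote: at
$d = 20, \epsilon = 0.005$, a column needs $k \le 15$ before the het
posterior reaches 0.95. Both are plain arguments to `model_config()`.
Because the non-reference pool spans three bases, the model is not symmetric
under exchanging reference and alternative for $\epsilon > 0$
($p_{AA} = \epsilon/3$ while $1 - p_{RR} = \epsilon$); the exact ref/alt
label symmetry holds at $\epsilon = 0$ and is property-tested there.

## Calibrating $\epsilon$ on a hemizygous control

A hemizygous gene (an X-linked single-copy gene in males) cannot be
heterozygous, so its pooled non-reference fraction estimates the combined
technical noise — sequencing error, library-preparation substitutions,
residual misalignment. `estimate_error_rate()` excludes columns whose
non-reference fraction exceeds `outlier_fraction` (default 0.2) before
pooling: such columns are more plausibly genuine variants, RNA edits or
position-specific artifacts, and leaving them in would inflate
$\hat\epsilon$ by orders of magnitude. Each sample × position column is an
exclusion unit, so a single sample's aberrant position cannot survive by
dilution across samples. The estimator is the pooled ratio, and on
simulations it recovers the generating $\epsilon$ within binomial
Monte-Carlo error of the pooled depth.

## Heterozygosity maps and recurrent artifacts

The per-sample, per-gene table of (position, reference fraction, call) is
the heterozygosity map. Uncovered positions are simply absent — never
imputed. Across a two-cohort study, a position whose calls span all possible
genotypes in *both* cohorts is overwhelmingly more likely a recurrent
technical artifact than a true polymorphism, and is excluded from het
counting. "Produces all possible genotypes in the majority of samples" is
ambiguous as an algorithm, so `flag_artifacts()` offers two explicit
operationalisations, both declared approximations of what a human curator
would do on the plots:

* **all-classes rule** (default): flagged when each cohort's non-missing
  calls contain all three classes;
* **majority rule**: flagged when at least `majority_frac` (default 0.5) of
  each cohort's called samples disagree with that cohort's modal call.

The all-classes rule is monotone — removing a sample can never flag a new
position — and cannot be triggered by genuine sex-linked heterozygosity
(females het, males hom gives only two classes). `count_het_sites()` then
counts non-flagged `het` calls per sample.

## Cohort comparison

Per-sample het-site burdens are compared between cohorts with a two-sided
permutation test on the difference in means. All
$\binom{n}{n_1}$ labelings are enumerated when there are at most $10^5$ of
them; otherwise `n_perm` random relabelings are drawn and
$p = (1 + \#\{|\Delta_{perm}| \ge |\Delta_{obs}|\})/(n_{perm}+1)$, which
cannot reach 0. A Fisher exact test on the 2×2 table of cohort ×
"any het site" is reported alongside as the coarser, tie-robust view. The
original study reported its cohort comparison qualitatively from the
heterozygosity plots; these two formal tests are this package's explicit
substitutes. Genes are analysed separately (test gene, negative control,
positive controls serve different roles); no cross-gene multiplicity
correction is applied by default and a Bonferroni adjustment is a one-liner
on the returned p-values.

When a sample sheet carries sex, non-male samples are excluded from the
comparison by default: in a male-silencing design a female is legitimately
heterozygous at PAR sites and belongs with the positive controls, not in
the test.

On sparse burdens (nearly all zeros, as under the null at strict calling
settings) the permutation distribution is heavily tied and the test is
conservative — its rejection rate sits below the nominal level rather than
at it. This is the expected behaviour of a permutation test on discrete
data; with non-degenerate counts its size is close to nominal, and both
regimes are covered by tests.

## The synthetic generator

`sim_scenario()` fixes the study conditions; `simulate_pileup()` realises
them. Reads originate from the reference-bearing allele with probability
$1-f$ and from the alternative-bearing allele with probability $f$ (the
reactivation fraction), then miscall with probability $\epsilon$ uniformly
onto the three other bases. The reference-read probability at a divergent
site is therefore

$$p_{ref} = (1-f)(1-\epsilon) + f\,\epsilon/3,$$

and $1-\epsilon$ elsewhere; the truth table records both the probability and
the class label (hom-ref at $f=0$, hom-alt at $f=1$, het otherwise). A bulk
transcript fraction $f$ is the only mixing parameter: a cell-mixture
reading (fraction of cells reactivated × within-cell allelic ratio)
collapses to the same $f$ and is not separately parameterised. The
reference sequence is a deterministic A/C/G/T cycle, so any two scenarios
over the same coordinates agree on reference and alternative bases by
construction, and by default the reference-bearing allele is the active
(X-linked) copy — silencing looks homozygous-reference. Female samples are
simulated as true heterozygotes ($f$ effectively 0.5) regardless of the
scenario's $f$, mirroring the use of a female sample as the positive
heterozygosity reference.

Two depth laws are provided. The fixed law puts depth $d$ at every position
(unit tests, closed-form comparisons). The range law draws each sample's
total mapped read count uniformly from 653–4033 — the range reported for a
*SPRY3*-length transcript in cerebellar RNA-seq libraries — and places each
read uniformly along the transcript covering `read_length` (default 100)
consecutive positions, so per-position depth is read coverage: a 2 kb
transcript then sees per-position depths of roughly 30–200, matching what a
real pileup at that read count looks like. Spreading reads as single-base
increments instead would give per-position depths near 1 and make every
column uncallable, which is why coverage, not count-spreading, is the
model. The realised read totals are returned (`read_totals`) and tested
against the configured range.

Determinism is a contract: the same scenario and seed give bit-identical
pileups. Fixtures round-trip losslessly through both on-disk formats
(mpileup text with a constant high base quality, and the counts TSV), and
the mpileup writer deliberately exercises the decoder's strand-merging,
read-start/read-end and indel paths.

What the generator does *not* emulate — and what passing tests therefore do
not establish about real data: alignment and mapping error (inputs are
assumed uniquely mapped; the multi-mapping filter is upstream), indels and
strand effects, position-dependent or context-dependent error rates,
overdispersed allelic ratios from transcriptional bursting, RNA editing,
and reference bias. The artifact-flagging stage exists precisely because
real pileups violate the homogeneous-error assumption at specific
coordinates.

## Power analysis

`power_analysis()` simulates the full pipeline per grid cell — cohorts,
classification, artifact flagging, burden counting, permutation test — and
reports three detection probabilities with binomial standard errors:
per-case-sample detection, any-sample detection, and cohort-test rejection
at $\alpha$. The detection event is a non-flagged call in {het, hom-alt} at
a divergent site: under the silencing design the active allele carries the
reference base, so *any* alternative-allele call evidences expression of
the silenced copy — at $f$ near 0.5 that evidence is a het call, at $f$
near 1 a hom-alt call. Defining detection on het calls alone would make
power non-monotone in $f$ (it would collapse as $f \to 1$), which is an
artifact of labelling, not of detectability. Replicates classify with the
cell's generating $\epsilon$; recalibrating from a simulated negative
control inside every replicate would only re-measure the (separately
tested) calibration stage at a large cost. Power is monotone in $f$, depth,
site count and cohort size within Monte-Carlo error, and the
fully-reactivated, error-free, high-depth cell detects every case sample.

## Problem sizes and runtime choices

The shipped tests run the model-expectation checks at 10,000 replicate
columns (depth 100), genotype-recovery at ~36,000 columns across the three
true classes, the null study as 1,000 replicates of a 20-vs-20 cohort over
a 30-position transcript with $\epsilon = 0.02$ and 199 permutations per
test, and the power surface as a 4 × 2 grid in ($f$, depth) at 5 divergent
sites, 6 samples per cohort, 40 replicates per cell. These sizes give
Monte-Carlo standard errors comfortably inside the asserted tolerances
while keeping the whole suite around two minutes on one core.

## Known limitations

* The classifier is per-column and per-sample; no joint multi-sample or
  multi-site genotyping, no phasing, no quality-weighted likelihoods.
* $\epsilon$ is a single scalar per analysis; genes with heterogeneous
  error profiles will be mis-calibrated at their extreme positions (the
  artifact filter is the backstop).
* The burden statistic ignores *which* positions are heterozygous;
  concordance of sites across samples is visible in the maps but not
  tested.
* With per-sample burdens that are almost all zeros the permutation test is
  conservative; the Fisher test on the any-biallelic table is the more
  informative read-out in that regime.
* The generator's truth labels classify any $0 < f < 1$ as heterozygous;
  at extreme $f$ (say 0.02) the optimal call for a finite column is
  genuinely hom-ref, so "accuracy against truth" is only meaningful at the
  moderate $f$ values used in the tests.
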