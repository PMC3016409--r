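---
title: "Pedigree-informed haplotype phasing and Monte Carlo association testing"
author: "hapmc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pedigree-informed haplotype phasing and Monte Carlo association testing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hapmc)
```

## The problem

Regional haplotype association studies test whether specific haplotypes
over a set of tightly linked SNPs (a candidate gene, or a follow-up
region from a genome-wide scan) are associated with disease.  Two
obstacles stand in the way when the study resource contains families:
phase must be inferred from unordered genotypes, and using
maximum-likelihood (MLE) haplotype assignments as if they were observed
is known to invalidate naive tests.  `hapmc` addresses both: it phases
genotypes with an EM algorithm that exploits pedigree structure, and it
obtains significance from a gene-dropping Monte Carlo null that re-runs
the *entire* phasing pipeline on every simulated null data set, so that
whatever bias MLE assignment introduces is present identically in the
observed and null statistics.  The method assumes a zero-recombination
autosomal region with mutation- and error-free biallelic SNPs, and is
practical up to roughly 20 markers.

## Phasing

**Preprocessing.** Large pedigrees with missing data make exhaustive
configuration enumeration intractable, so each pedigree is first split:
a nuclear family is retained for phasing when both parents and at least
one offspring have a sufficient fraction of non-missing genotypes (the
`min_genotyped_fraction` threshold, default 0.5 — the original method
leaves this to the user; 0.5 is our default).  Retained families sharing
members are reconnected into fragments; members of no retained family
are phased as independent individuals if sufficiently genotyped and are
otherwise excluded from phasing.  They are never excluded from the
Monte Carlo structure (see below).

Each individual's genotypes are then loaded into six locus-length bit
vectors — homozygous, heterozygous, unphased for the genotype, and set,
missing, value (minor-allele indicator) for each haplotype — and
parent-offspring trios are swept with deterministic rules implemented as
whole-vector logical operations: parental homozygous loci resolve
offspring phase and missingness, offspring homozygous loci resolve the
transmitted parental haplotype, and inheritance/transmission bits are
resolved by exclusion (a haplotype that cannot have come from one parent
must have come from the other).  Once a parent-offspring pair's shared
haplotype is identified, set alleles are copied in both directions
(under zero recombination the transmitted chromosome is passed intact).
Two conventions matter: when either haplotype of a still-symmetric
individual could receive an update, haplotype 1 is chosen (deterministic
and label-symmetric), and the final heterozygous locus of an individual
whose other set loci are all homozygous is phased arbitrarily, which is
safe precisely because the two phase choices give the same unordered
pair.  Every rule fires only when the deduction is forced; an ambiguous
prose rule from the original description is skipped rather than guessed.
The test suite verifies on hundreds of random pedigrees that the
configurations implied by the processed states are *exactly* the
Mendelian-consistent set — preprocessing removes no valid configuration
and admits no invalid one.

**Configuration enumeration.** Remaining ambiguous positions are
expanded into all consistent haplotype pairs per individual; nuclear
family configurations are built starting from the offspring with the
fewest possibilities, discarding Mendelian-inconsistent partial
configurations as they arise (genotype elimination integrated into
construction); fragments are assembled by joining family configuration
lists on the linking individuals' haplotype pairs.  Within a
configuration a child's pair is ordered (maternal, paternal); founder
pairs are unordered and stored canonically so phase-symmetric founder
configurations are not double-counted (the likelihood is invariant).  A
hard cap (5e6 stored partial configurations) aborts pathological
enumerations with advice to raise the genotyping threshold.
Single-nuclear-family fragments — the overwhelmingly common case inside
the Monte Carlo loop — are enumerated in compiled code; the test suite
asserts both paths equal a brute-force oracle.

**EM.** Under Hardy-Weinberg equilibrium and Mendelian transmission,
the likelihood of a pedigree's genotypes given population haplotype
frequencies H factorises over configurations into founder pair
probabilities (f(h)^2, or 2 f(h1) f(h2) for heterozygous pairs) and
transmission probabilities (1/2 per heterozygous transmitting parent).
The E-step computes each configuration's posterior within its fragment;
the M-step divides expected founder-chromosome counts by twice the
number of founders and independents (descendant chromosomes are copies
of founder chromosomes and are not counted — this matches the
factorisation in which only founder pairs carry H).  Initial
frequencies are uniform over the haplotypes appearing in at least one
configuration; iteration stops when the largest frequency change falls
below `tol` (default 1e-6, `max_iter` 1000).  The log-likelihood is
non-decreasing across iterations and the frequencies remain a
probability distribution — both asserted by property tests.  Each
individual's MLE pair is read from the maximum-posterior configuration
of its fragment, with ties broken by the lexicographically smallest
configuration, so results are reproducible bit-for-bit.  Missing
positions are thereby imputed.

**Partition-ligation.** For marker sets longer than `partition_len`
(default 5), overlapping windows (`overlap` 1) are phased separately,
haplotypes with frequency below `cutoff` (1e-6) are pruned — keeping the
`buffer` (25) highest-frequency haplotypes below the cutoff — and
windows are ligated progressively left to right: surviving haplotypes of
adjacent regions are concatenated where they agree on the overlap, the
enumeration is re-run restricted to the surviving concatenations, and
the EM is re-initialised uniformly over them (the original description
does not say which estimates seed the ligated EM; uniform
re-initialisation keeps every stage a plain EM).  If the restriction
leaves an individual or family with no consistent configuration, its
genotype-consistent haplotypes are reinstated and the enumeration is
retried once before a degeneracy error is raised.  With `cutoff = 0`
and an unbounded buffer the procedure provably reproduces the
single-block EM (tested to 1e-6).

## Association testing

Statistics are computed on the MLE haplotype data as pure test
statistics — no asymptotic p-values are ever reported, because the MC
null supplies significance.  Available: the Cochran-Armitage trend test
(diploid copy-count coding with scores 0, 1, 2 — the scores are our
choice, the usual additive convention), Pearson chi-square and odds
ratio (haploid chromosome counts, or diploid carrier-collapsed 2x2;
Haldane's 0.5 correction with a flag when a cell is empty), and the TDT
((b - c)^2 / (b + c) over transmissions from informative parents —
exactly one target haplotype — to affected offspring, counted once per
parent-offspring pair, transmissions read from the MLE configuration).
Any locus subset can be analysed; sub-haplotypes are positional
projections of the full-length MLE pairs, so imputed positions carry
through.

Controls are either explicit (every genotyped unaffected individual) or
pseudocontrols: for each affected case whose parents are both genotyped
and unaffected, the two untransmitted parental haplotypes form one
pseudocontrol that *replaces* the parents' explicit-control roles; all
other unaffected individuals remain explicit controls, which is what
makes the mode usable in large pedigrees of mixed composition.  A case
whose transmission the MLE configuration cannot resolve (e.g. its
family was split during phasing) contributes no pseudocontrol and its
parents stay explicit.

## The Monte Carlo null

Null data sets are produced by gene-dropping on the *full* pedigree
structures (splitting is a phasing device only): founders and
independents draw two haplotypes i.i.d. from the frequencies estimated
on the observed data, descendants receive one haplotype from each
parent uniformly, the observed missing-data mask is imposed — after
individuals below the genotyping threshold have been coded completely
missing, so observed and null present identical missingness — and phase
is discarded.  Each null data set is then phased with the same pipeline
and settings as the observed data and the statistic recomputed.  The
empirical p-value uses the add-one convention, p = (1 + #{null >=
observed}) / (1 + n_null), with ties counted toward the null tail
(conservative) and odds ratios compared as |log OR|.  Phasing failures
on a null (possible only in degenerate partition-ligation corners) are
redrawn and logged; more than 1% redraws aborts the run.  A single seed
governs the whole run.

Caching note: configuration enumeration is a deterministic function of
a fragment's structure and genotypes, so enumeration tables are shared
across null replicates; the EM, MLE extraction, and statistics are
recomputed for every null, which is what the validity argument
requires.

## The simulation designs

`simulate_design()` reproduces the validation designs.  A packaged pool
of 15 haplotypes over 15 biallelic markers (distinct 4-locus prefixes,
low pairwise marker correlation, mimicking a regional tagging-SNP
panel) supplies founder chromosomes; truncation to fewer loci preserves
all 15 haplotypes and the risk-haplotype frequency.  The designated
risk haplotype's frequency q is a parameter (0.04-0.17 in the original
study).  A hidden disease SNP is assigned per founder chromosome with
P(A | risk hap) = q + r(1 - q) and P(A | other) = q(1 - r), r =
sqrt(r2); setting the dSNP marginal frequency equal to q is our choice
— it is the unique symmetric calibration that makes r the sole LD
parameter while preserving the marginal.  Penetrance is multiplicative,
sporadic * GRR^g with a 5% sporadic rate.  Designs: CC (500 cases / 500
controls), TRIO (500 case-parent trios, child affected), ASP (250
families, both sibs affected), LP1/LP2 (five-generation high-risk
pedigrees, at least 14 cases, top two generations fully missing,
controls sampled as 80% close relatives of a case — 50% parents, 30%
siblings — and 20% beyond first degree, to ~2x or ~1x the case count).
Parental phenotypes in TRIO/ASP are drawn from the penetrance model
unconditionally (unstated in the original; the natural choice).  The
LP pedigree template (sibship sizes 4/3/2/2 down the generations,
spouses marrying in, 130 members) matches the published topology only
qualitatively — the exact figure is not recoverable from text, which is
why large-pedigree power cells are not asserted quantitatively.  Null
data use GRR = 1 (genotypes then independent of phenotype by
construction); null large pedigrees cluster phenotypes under an
alternative model (GRR 1.5, q 0.10 by default) while genotypes are
re-dropped independently.

What the generator does *not* emulate: real LD matrices from a
reference panel (users may supply their own frequency table),
genotyping error, recombination, and X-linked inheritance.  Passing
tests therefore demonstrate correctness of the machinery under the
stated model, not robustness to violations of it.

## Problem sizes used in the tests

The original validation used 1000 replicates x 1000 null configurations
on full-size resources per cell — hours to days of compute per table.
The package's checks run the same code at reduced scale and recompute
every comparison band for the scale actually run: type-I error on a
50v50 case-control resource (200 replicates) and 25 trios (100
replicates), each with a 39-null Monte Carlo grid — chosen because
(1 + k)/40 <= 0.05 is attainable exactly at k = 1, so the nominal size
is exactly 5% — judged against the binomial 95% band for those
replicate counts; power for the case-control design at q = 0.17,
GRR = 2.0 at full size (500/500, 15 replicates, 99 nulls); p-value
uniformity by Kolmogorov-Smirnov over 200 replicates.  One caveat
worth stating: on very small resources (say 15v15 subjects) the trend
statistic is often exactly zero and tied with many nulls, so the
empirical p piles up at 1 — the test is then conservative, not
invalid; the uniformity check is run at a size where the statistic is
non-degenerate.  Configuration enumeration is checked against a
brute-force enumerator on 500 random pedigrees (up to 10 members, up
to 6 loci, varying missingness).  The acceptance script
(`scripts/acceptance.R`) re-runs the type-I checks at the largest sizes
that fit a single-CPU run of a few minutes (100v100 case-control
subjects over 120 replicates; 50 trios over 60 replicates), the power
cell at full size with a 59-null grid, and the phasing-accuracy
comparison on affected-sib-pair resources with 5% missingness.

## Known limitations

Marker sets beyond ~20 loci are impractical (state-space growth);
point estimates of effect size from ascertained pedigree data remain
upwardly biased even though their p-values are valid — interpret odds
ratios with caution; inbreeding loops are not supported (families with
cycles are rejected at parse time); multi-allelic markers, X-linked
inheritance, recombination, and genotype-error modelling are out of
scope.
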