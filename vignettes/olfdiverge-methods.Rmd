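---
title: "Models and methods behind olfdiverge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind olfdiverge}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(olfdiverge)
```

`olfdiverge` compares the chemosensory gene repertoires of two sibling
mosquito species along three axes — coding-sequence divergence, transcript
abundance, and modelled whole-antenna odorant receptivity — and ties them
together with orthology reconciliation and a pseudo-reference mapping
correction. This vignette explains each model, the choices made where the
design was genuinely open, and what the synthetic-data tests do and do not
establish.

## Codon-counting divergence statistics

All divergence statistics operate on a `codon_pair`: two aligned coding
sequences split into codon columns, with every column containing a gap or
a stop codon in either sequence dropped pairwise (`prepare_pair` reports
each dropped column and why). Positions of retained columns in the
*reference* (first) sequence's ungapped protein are recorded so
membrane-topology annotations, which are expressed in ungapped protein
coordinates, can be applied later.

**Protein distance.** The proportion of differing residues p, optionally
Poisson-corrected to d = −ln(1 − p) (the default). Saturation (p ≥ 1) is
reported as an explicit flag rather than an infinite value.

**dN/dS.** A Nei–Gojobori-style counting estimator. Each codon position
contributes up to one site, split 1/3 per possible nucleotide change into
synonymous and nonsynonymous fractions; changes that would create a stop
codon are disregarded, so a codon can hold slightly fewer than three
countable sites. Site counts are averaged over the two sequences. For
codons differing at k > 1 positions, observed synonymous and
nonsynonymous differences are averaged over the k! minimal mutational
pathways, excluding pathways that pass through a stop codon (all pathways
are used, with stop steps scored nonsynonymous-radical, in the degenerate
case where every pathway is blocked — this case does not arise for
sense-codon pairs under the standard code, which we verified by
exhaustive precomputation). Proportions are Jukes–Cantor corrected,
d = −(3/4)·ln(1 − 4p/3); p ≥ 3/4 flags the rate undefined, and ω = dN/dS
is flagged undefined when dS = 0. A maximum-likelihood codon model would
be the natural alternative; the counting estimator was chosen because it
is deterministic and exactly checkable against a brute-force enumeration
oracle, which the test suite exploits, and is adequate for pairwise rate
ratios between very close species.

**dR/dC.** Nonsynonymous sites are further partitioned into radical and
conservative fractions by the Dayhoff residue classes
{AGPST, DENQ, HKR, ILMV, FWY, C}: each possible single-nucleotide
amino-acid change contributes 1/3 of a site to the class of that change.
Observed nonsynonymous differences are classified with the same pathway
averaging as dN/dS, each nonsynonymous step scored by the Dayhoff classes
of its two residues. p_R = O_R/N_R and p_C = O_C/N_C are Jukes–Cantor
corrected and dR/dC is flagged undefined when dC = 0. Counting is done at
the codon level (an alternative would be protein-level counting; codon
level was chosen for consistency with the dN/dS machinery and because it
uses the same mutational-opportunity denominator). The partition is a
parameter, so other residue classifications can be substituted.

**Region and charged-residue profiling.** Each differing residue column
is assigned a region (e.g. TM / inside / outside) through the reference
sequence's ungapped position; radical and conservative changes are
tallied per region. A substitution counts toward the "charged" tally when
either residue belongs to a configurable set whose default is
{E, N, Y} — the set follows the source convention for residues implicated
in receptor function even though N and Y are not chemically charged; it
is a knob, not a hard-coded assumption. Annotations are anchored to the
first sequence deliberately: topology predictions exist for the reference
species' proteins, and anchoring makes the profile reproducible from one
annotation file.

## Orthologous groups and gain/loss reconciliation

An orthologous group (OG) is a clade of the gene tree, with bootstrap
support strictly above the threshold (default 90), whose gene content is
consistent with a single gene in the species' common ancestor: one gene
per species, or k > 1 genes of one species forming a monophyletic block
with at most one gene of the other. Within an OG, k genes of one species
imply k − 1 gains on that species' branch; a species absent from an OG is
one loss. Nodes carrying no support value (the root of most tree files)
are treated as supported, since absence of a bootstrap value is not
evidence against a clade. Clades failing support or content are resolved
by descending into their children; multifurcations are descended through;
a leaf reached this way becomes a singleton OG scored as
ancestral-present plus a loss in the absent species — the alternative
(scoring singletons as gains) was rejected because a genuine
species-specific duplicate would cluster with a within-species paralog
rather than stand alone. Only the support of the OG-defining clade
matters; supports inside a duplication block are not part of the OG
definition. Input trees are used as rooted; an optional midpoint-rooting
flag covers the common case of unrooted maximum-likelihood output. The
per-family summary enforces the bookkeeping identity
count_s = n_OGs + gains_s − losses_s, so inconsistent reconciliations
cannot pass silently.

## RPKM and the reliable fold change

RPKM = 10⁹ · count / (library_size · gene_length). "Detectable" defaults
to a positive count, with an optional RPKM floor for analyses phrased in
abundance terms.

The single-replicate fold change treats each gene's rate in each sample
as Poisson with a flat Gamma prior, so the posterior is
Gamma(count + 1) scaled by library size. The posterior of
z = log2(rate_b/rate_a) is sampled by Monte Carlo (default 10⁵ draws,
deterministic given the seed); with q_lo and q_hi the (1 − c) and c
quantiles, the reported value is q_lo if q_lo > 0, q_hi if q_hi < 0, and
0 otherwise, at credibility c = 0.99 by default. Zero therefore means
"no reliable difference", and any non-zero value is a conservative bound
whose magnitude never exceeds the raw log2 ratio. Sampling uses `rgamma`
rather than inverse-CDF evaluation, which is an order of magnitude
faster at these draw counts; the estimator is identical in distribution.
This is a same-spirit reimplementation of the reliable-fold-change idea
for replicate-free designs, not a bit-compatible clone of any external
tool: the prior and the library-size normalization are documented here
precisely because external implementations leave them implicit. The raw
log2 ratio is reported as an explicit undefined flag when either count is
zero; the reliable value remains defined.

Two-sided significance at c = 0.99 implies roughly a 2% false-positive
rate on null genes, which the calibration tests bound at 2.5%. Quartile
contrasts split genes at the quartiles of their dN/dS ratio and compare
|fold change| between the most conserved quartile and the rest with
two-sided Wilcoxon rank-sum tests (normal approximation, since ties are
expected); all-identical ratios are flagged degenerate rather than cut
into arbitrary quartiles.

## Pseudo-reference construction

Fixed interspecific differences are substituted into the reference so the
second species' reads can be mapped without reference-allele bias. Only
single-nucleotide variants passing read depth ≥ 5 and variant quality
≥ 60 (both read as inclusive minima; both configurable) are applied, each
with its most frequent alternative allele, ties broken alphabetically and
logged. Indel and multi-nucleotide records are skipped with a warning —
substitution must never change coordinates. Positions are 1-based as in
VCF. A stated reference allele that does not match the sequence is a hard
error, which doubles as a guard against accidentally applying the same
variant set twice. Depth is taken from the DP field and quality from
QUAL; sites' allele counts come from AC.

## The antennal receptivity model

The deorphanization panel (receptor × odorant, Δ spikes/s over baseline)
is first filtered: receptors whose maximum response is below
100 spikes/s are removed, then odorants whose maximum over the surviving
receptors is below the same threshold. The order — receptors first, then
odorants — is fixed and logged. Each surviving response is weighted by
the receptor's RPKM in a species and summed per odorant:
A_s(o) = Σ_r RPKM_s(r) · max(response(r, o), 0). Odor-induced decreases
in spiking are indeterminate and contribute exactly zero; missing cells
are treated as zero after filtering and counted. The same (reference
species) response matrix is weighted by both species' abundances — the
model assumes functional conservation of orthologous receptors, which is
the key caveat of the whole construction.

The interspecific change is the ratio ρ(o) = A_g(o)/A_q(o), reported both
raw and as a symmetric signed percent (100·(ρ − 1) for ρ ≥ 1,
−100·(1/ρ − 1) otherwise) so a doubling and a halving plot at ±100; the
plotted quantity in comparable published figures is not defined
unambiguously, so both are always emitted. Odorants within ±10% are "no
change"; zero receptivity in both species is flagged undefined; zero in
exactly one species is reported as one-sided (infinite-percent)
enrichment. Class enrichment builds, per chemical class (or for the
human-associated flag), the 2×2 table of in-class/out-class ×
enriched-in-species over the odorants outside the no-change band,
optionally restricted to changes larger than a percent floor, and applies
a two-sided Fisher exact test summing hypergeometric probabilities no
larger than the observed table's (with the conventional 1 + 10⁻⁷ guard
against floating-point ties). Strata with no odorant in the tested set
are flagged, not tested.

## What the synthetic generators emulate — and what they do not

The generators produce every input the pipeline reads, with ground truth
recorded beside each dataset, and are pure functions of their arguments
including the seed.

* `simulate_codon_pair` evolves two descendants from a uniform-sense-codon
  ancestor; proposals per position (default 0.08 per branch) are accepted
  fully when synonymous, with probability proportional to ω when
  nonsynonymous, and the accepted change's Dayhoff class is drawn from
  the planted radical bias. Uniform codon usage, no rate heterogeneity,
  no indels, no selection on specific sites.
* `simulate_counts` draws log-normal baseline rates (sdlog 0.25) around a
  mean depth of 200 and Poisson counts; a `de_fraction` of genes (default
  0.5 — in these antennal repertoires the majority of detectable
  chemosensory genes differ between the species) receives a symmetric
  ±2 log2-fold shift. No overdispersion beyond Poisson, no length bias,
  no multi-mapping.
* `simulate_gene_trees` emits one tree per orthologous group with all
  supports at 100, at most one gain and one loss per OG, and never a loss
  in the species that gained — exactly the regime in which
  reconciliation is identifiable, which is what makes exact recovery a
  meaningful contract. Real trees have noisy topologies and supports;
  recovery there is *not* claimed.
* `simulate_response_matrix` plants a class-confined species bias: a
  third of receptors are specialists tuned exclusively within the biased
  class (default esters, a quarter of a 48-odorant panel — typical
  deorphanization panels are ester-rich) with a 4-fold abundance tilt,
  while background receptors come in antithetic pairs with equal baseline
  abundance and mirrored mild tilts, making the non-planted classes
  symmetric by construction. This is a designed power scenario, not a
  model of real tuning curves.
* `simulate_variants` spans the depth-5/quality-60 filter boundaries and
  sprinkles in indel records that a correct implementation must skip.

Passing tests on these generators establishes that the pipeline's logic
is correct under its own assumptions; it does not establish robustness to
alignment error, annotation error, overdispersed counts, or receptor
functional divergence.

## Problem sizes and numerical choices

The test suite and the acceptance script use: exhaustive
estimator-vs-oracle sweeps over all codon-sequence pairs of up to three
codons from a six-codon alphabet chosen to sit adjacent to stop codons,
plus 200 random ten-codon pairs over the full sense alphabet; 50
replicates of 3000 codons per planted ω; 2000-gene count tables with
2 × 10⁴ posterior draws per gene; 500 simulated orthologous groups; an
exhaustive Fisher-vs-enumeration sweep over all 2×2 tables with N ≤ 40;
and 100 seeded replicates of the planted-enrichment power run. These
sizes keep the complete suite under a couple of minutes on one CPU while
leaving the statistical margins comfortable.

Ratios with zero denominators (ω with dS = 0, dR/dC with dC = 0,
receptivity with A_q = 0) are explicit flags or one-sided labels, never
raw infinities, so all tables serialize cleanly. All stochastic functions
take a seed and restore the caller's RNG state.

## Known limitations

* The counting dN/dS is not a maximum-likelihood estimate; no transition/
  transversion bias, codon-frequency, or rate-variation corrections are
  applied, and no test of positive selection is offered.
* Reconciliation handles exactly two species and assumes at most one loss
  per species per OG; duplication–transfer–loss models are out of scope.
* The fold change has no multi-replicate mode and no normalization beyond
  library size.
* The receptivity model inherits every assumption of its inputs: ligand
  panels are incomplete, heterologous responses imperfectly proxy in vivo
  sensitivity, and orthologous receptors are assumed functionally
  equivalent.
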