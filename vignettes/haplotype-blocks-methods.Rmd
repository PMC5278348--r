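---
title: "Haplotype blocks, diversity and haplotype-based association: methods"
author: "hapblocks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Haplotype blocks, diversity and haplotype-based association: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hapblocks)
```

## Scope and data model

`hapblocks` analyzes SNP diversity panels of self-pollinating crops (wheat
is the motivating case) genotyped on a genetic map in centimorgan. The
substrate is a `genotype_panel`: a lines x SNPs matrix of biallelic calls
with states *allele0*, *allele1*, *heterozygous* and *missing*, plus a map
assigning every SNP to exactly one chromosome location. SNPs are kept
sorted by (chromosome, cM, SNP id); co-located markers (identical cM) are
legal — dense array maps produce them, and zero-span blocks are real.

Because the panels are inbred lines, a homozygous call is one observable
haplotype allele: all frequency computations count each line once
(haploid-equivalent counting; diploid counting would only rescale).
Heterozygous calls, rare leftovers of residual heterozygosity or clustering
artifacts, are treated as missing by default throughout LD, block,
haplotype and painting code. This is a package choice (array pipelines do
not document a canonical treatment): phase-free haplotypes require
homozygous calls, and the flag is exposed (`het_as_missing`) where the
convention is cheap to relax.

## Linkage disequilibrium on inbred panels

Two-locus haplotype frequencies are counted directly from lines homozygous
and non-missing at both SNPs — no EM phasing is required. With alleles
`A/a`, `B/b`:

* `D = p_AB - p_A p_B`
* `D' = |D| / D_max`, `D_max = min(p_A p_b, p_a p_B)` for `D > 0`,
  `min(p_A p_B, p_a p_b)` for `D < 0`
* `r^2 = D^2 / (p_A p_a p_B p_b)`

The unsigned `|D'|` is used (the block rule below is sign-free). Missing
data are handled by pairwise-complete deletion and the informative-line
count is recorded. Pairs observed in fewer than `min_informative = 5` lines
are treated as uninformative: `D'` is unstable at tiny counts, and the
source tooling's internal minimum counts are version-specific and
undocumented, so the package fixes a conservative default and exposes it.

## Solid-spine haplotype blocks

A run of consecutive mapped SNPs `[i..j]` is a valid block when the first
and the last marker are in strong LD (`|D'|` strictly greater than the
threshold, default 0.8) with every intermediate marker and with each other;
the intermediate markers need not be in LD with one another. Blocks are
grown by a deterministic greedy left-to-right scan (start at the leftmost
unblocked SNP, extend the right edge while the interval stays valid, emit
at length two or more, continue after the block). Undefined LD counts as
failing the threshold. Minimum block size is two SNPs; there is no maximum
span; zero-span blocks are allowed.

This fixes exact semantics that the GUI tooling tradition (Haploview-style
"solid spine of LD") leaves partly unspecified. The scan and its validity
predicate are verified in the test suite against a brute-force interval
oracle on hundreds of seeded small `|D'|` matrices, and every emitted block
is re-checked post hoc against the predicate. Confidence-interval (Gabriel)
and four-gamete block definitions are out of scope.

Haplotypes are the distinct complete strings over a block's members among
informative lines, numbered by descending frequency with lexicographic
tie-breaks; a line missing any member call is unassigned rather than a new
haplotype. Tag SNPs are chosen greedily: at each step the member SNP
resolving the most still-confounded pairs of common haplotypes (frequency
at least 0.05) is added, ties to the leftmost marker. Greedy set cover is
not guaranteed minimal in general; on the constructed blocks in the test
suite it matches the brute-force minimum.

Per-chromosome summaries report, per chromosome: SNP counts, SNPs in
blocks, tag SNPs, block count, mean and range of spans, haplotype totals.
Genome aggregates are emitted under *both* span conventions found in the
literature — the block-count-weighted mean per genome and the unweighted
mean of per-chromosome means — because published summary tables print
either without flagging which; the two are labeled explicitly.

## Diversity and differentiation

Gene diversity is `1 - sum(p_i^2)`; PIC is Botstein's
`1 - sum(p_i^2) - sum_{i<j} 2 p_i^2 p_j^2`. Both accept SNP alleles or
block haplotypes as the allele set. Differentiation is Nei's
`Gst = (Ht - Hs)/Ht` with `Hs` weighted by informative line counts (the
POPGENE convention; published analyses of this kind name the tool but
not the weighting) and `Ht` from the pooled weighted frequencies.

A caution that matters for interpretation: with `k` demes drawn from a
Balding–Nichols model at parameter `F`, the expectation of pooled-panel
Gst is approximately `F (1 - 1/k) / (1 - F/k)` — about `F/2` for two demes.
Recovering `F` itself therefore requires several demes; the package's
parameter-recovery study uses ten populations of 100 lines, where the
expectation is within 0.013 of `F`. Two-population Gst values are
faithful descriptive statistics, but they are not estimates of `F`.

The sliding-window profile shifts a window of three consecutive blocks
along each chromosome one block at a time (map order, short arm to long
arm). The window index is the arithmetic mean of the three blocks'
within-population haplotype gene diversities; whether published profiles of this
kind pooled the window's haplotypes instead is not documented, so the pooled
joint-haplotype variant is offered as `mode = "pooled"`. The window
midpoint is the mean of the three block midpoints. Within-population
haplotype frequencies are recomputed from that population's lines only.

## Kinship, structure and BLUP

Kinship is the Loiselle et al. multilocus estimator on allele-frequency
deviations, pairwise-complete over shared loci, with the finite-sample
correction `p(1-p)/(n-1)` per locus. Negative pair estimates are set to 0
(they indicate a lower-than-random relationship) and the diagonal is fixed
at 1 by convention, recorded in the matrix's `diagonal` attribute. The
permutation significance test of the original estimator is omitted: it
feeds nothing downstream.

Structure covariates are the top principal-component scores of the
centered dosage matrix. Model-based ancestry (STRUCTURE-style MCMC with
ad hoc K selection) is deliberately replaced: the covariates enter the
mixed model only as fixed regressors, PCA supplies equivalent axes
deterministically at desk scale, and user-supplied matrices are accepted
anywhere a `Q` is taken. The number of axes is unconstrained (`q`
columns, not `k - 1`); two axes are the package default in examples.

Multi-environment trait values are combined by REML BLUP
(`value = mean + environment + line + error`, line random; fitted with
`lme4`), and heritability is reported as
`h^2 = sigma_a^2 / (sigma_a^2 + sigma_e^2)` from that fit's variance
components — the proportion of line variance over line-plus-residual.

## Mixed-model association (Q + K, P3D)

The association model is `y = mu + Q gamma + m beta + u + e` with
`u ~ N(0, sigma_a^2 K)`. Variance components are estimated once on the
null model (no marker) by REML profiled over the single ratio
`delta = sigma_e^2 / sigma_a^2`, using the eigendecomposition of `K` to
make the profile likelihood a one-dimensional optimization (optimize plus
a coarse grid guard against local maxima; convergence tolerance is the
square root of machine epsilon on the log-ratio scale). Those components
are then reused for every marker — the P3D scheme. No-compression is the
only mode: compression levels are a runtime device, P3D is the
approximation that matters, and the suite bounds its cost directly
(|delta log10 p| <= 0.2 against full per-marker REML on seeded fixtures).

Numerical choices: `K` is symmetrized; eigenvalues moderately below zero —
an expected by-product of the negatives-to-zero clipping rule — are
repaired by a diagonal spectrum shift, which is model-equivalent because
`sigma_a^2 (K + cI) + sigma_e^2 I` reparameterizes the same covariance;
a matrix whose smallest eigenvalue is worse than `-0.25` times the largest
is rejected. Markers genotyped on every phenotyped line use the
precomputed rotation; a marker with missing lines is handled by omission,
re-factoring `K_ss + delta I` on the observed subset with the null ratio
reused so the F-test compares nested models on identical data.

Single-SNP scans code inbred dosage 0/1 and test one coefficient;
haplotype-block scans code the block as indicator columns against the most
common haplotype, pooling classes rarer than 0.05 into `other` (published analyses filter
blocks by MAF but leave within-block rare classes unspecified),
and test the columns jointly. Block MAF is the frequency of the
second-most-common haplotype. Significance uses the marker-count rule
`P < 1/n` with the threshold rounded to two significant digits and its
negative log10 taken from the unrounded `1/n` (rounded to two decimals) —
the convention that reproduces the printed pairs (2.3e-4, 3.65) and
(1.2e-3, 2.93). Reported `R^2` is one-way ANOVA `SSA/SST` of the phenotype
grouped by marker class, computed outside the mixed model, and the
favorable allele/haplotype is the class with the largest trait-improving
mean, with the improvement direction a per-trait configuration
(`larger_favorable`) because per-trait orientations are not printed
anywhere authoritative.

## Founder painting

`paint_against_founder` marks every MAF-filtered SNP of every line as
*same* (green), *different* (yellow) or *missing* (white) against a named
founder line; SNPs where the founder is missing are unpaintable.
`block_transmission_summary` reports, per line and block, the fraction of
painted member SNPs in the founder state; the 0.9 call threshold for
"founder-type" is a package default (the visual classifications it mirrors
were never given a number). Painting is identity-in-state, not IBD.

## The synthetic panel generator

The generator exists so that every stage is testable without restricted
panel data. It emulates: two or more inbred subpopulations at a tunable
Balding–Nichols differentiation `F` (per-block haplotype frequencies drawn
`Dirichlet(p_anc (1-F)/F)`, whose aggregation property makes every SNP
marginal exactly biallelic Balding–Nichols); block-structured LD on a cM
map (founder haplotype pools built on a perfect phylogeny — each SNP
mutates on exactly one branch — so no within-block SNP pair shows four
gametes and planted blocks are solid spines by construction); free
recombination between blocks and none within (optionally a single
breakpoint rate); selection plans that fix one haplotype in one
subpopulation over an interval; and multi-environment phenotypes with
block- or SNP-resident QTL, a polygenic term built from small effects
across SNPs (optionally confined to named chromosomes) scaled to a target
heritability, and iid residuals.

Defaults mirror a wheat mini-core collection design: 157
landraces and 88 modern cultivars, differentiation `F = 0.06` (the
landrace-vs-modern range), four trial environments, heritability 0.6,
four haplotypes per block (matching the observed mean of ~4.2), 2% missing
calls. Where no value is stated the defaults are desk-scale choices: two
chromosomes of 120/100 SNPs, blocks of 4–8 SNPs spanning 0.2–2.5 cM with
2–6 cM gaps.

What the generator does **not** emulate: admixed lines, ascertainment bias
of array SNP panels, within-block mutation recurrence, polyploid
homoeology (panels are analyzed as diploid-inbred, as array data are
called), linkage between blocks, and genotyping error beyond missingness.
Passing tests on generated panels therefore demonstrate correctness of the
algorithms under the stated model, not robustness to every artifact of
real array data.

## Validation studies shipped with the package

The acceptance suite (and `scripts/acceptance.R`, which recomputes the same
quantities from scratch) runs:

* aggregation of the bundled published wheat 9K per-chromosome block
  summary, reproducing its printed totals, percentages and both mean-span
  conventions;
* the `1/n` significance thresholds for 4434 SNPs and 847 blocks;
* exhaustive-count LD oracles on 200 random two-SNP fixtures and
  brute-force block enumeration on 300 seeded `|D'|` matrices of up to 10
  SNPs;
* Gst recovery of a planted `F = 0.15` over 500 loci in ten demes of 100
  lines (see the multi-deme caveat above) and heritability recovery of a
  planted 0.6 with 200 lines in four environments;
* mixed-model type-I error at 0.05 on 2000 truly null markers: the
  polygenic background is confined to chromosomes the scan does not test,
  because markers on a background-carrying chromosome tag their
  block-mates' effects (proximal contamination) and would mildly inflate
  the rate — the usual leave-one-chromosome-out argument;
* the block-beats-SNP detection experiment: a QTL planted on an "interior"
  haplotype — the middle node of a three-haplotype mutation chain, which no
  single member SNP separates from both alternatives — with pooled
  frequency 0.05–0.12, flanking haplotypes at 0.30 or more, worst-case
  SNP-to-causal `r^2` at most 0.09, and an effect of 1.7 trait units on a
  300-line, 1600-SNP panel. These values come from a power analysis: the
  worst-case single-SNP `r^2` has a floor near `f/(1-f)` at balanced
  flanks, so a rare interior haplotype is what makes a block detectable
  while every member SNP stays below its own `1/n` threshold. Success is
  scored per replicate as "block significant and no member SNP
  significant", and at least 70% of 20 seeded replicates must succeed.

Problem sizes throughout (hundreds of lines, hundreds to a couple of
thousand markers, 3–20 replicates) are the package's chosen desk-scale
study conditions; they keep every study exactly reproducible from a single
seed.

## Known limitations

* Spine-scan semantics are fixed by this package; agreement with any
  specific Haploview build's greedy path, pairwise-deletion details or
  rare-genotype handling cannot be guaranteed from the published record.
* Gst with few demes underestimates the Balding–Nichols `F` (see above).
* P3D is an approximation; the suite bounds it empirically on desk-scale
  fixtures rather than proving it.
* Greedy tag selection can exceed the minimal cover on adversarial blocks.
* The painting is identity-in-state; shared ancestry is not distinguished
  from identical-by-state coincidence, which matters for rare alleles.
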