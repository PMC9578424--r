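---
title: "Models and methods behind mutaccum"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mutaccum}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mutaccum)
```

`mutaccum` implements the statistical core of a bacterial
mutation-accumulation (MA) and experimental-evolution workflow: rate
estimation with exact Poisson intervals, spectrum and neutrality tests,
gene-level selection scans, bottleneck drift arithmetic, plating
phenotypes, and simulators that generate all inputs. This vignette explains
each model, its assumptions, the tunable parameters, and the design
decisions taken where several constructions were defensible.

## Mutation-rate estimation

For lines $i = 1, \dots, n$ with analyzed sites $N_i$ and cell divisions
$T_i$, the mean rate per nucleotide site per cell division is

$$\hat\mu = \frac{m}{\sum_i N_i T_i},$$

with $m$ the total number of events of the requested class. The SEM is the
sample standard deviation (with $n-1$ denominator) of the per-line rates
$m_i/(N_i T_i)$ divided by $\sqrt n$. Confidence intervals are exact
(Garwood) Poisson intervals obtained from chi-square quantiles,

$$\left[\tfrac12 \chi^2_{\alpha/2}(2m),\;
       \tfrac12 \chi^2_{1-\alpha/2}(2m+2)\right] / \textstyle\sum_i N_i T_i,$$

with the lower bound defined as 0 when $m = 0$. Exact intervals guarantee
*at least* nominal coverage for every true mean; like all exact Poisson
intervals they are conservative, with true coverage above the nominal 95%
(markedly so at small event counts, approaching the nominal level only as
the mean grows). We use them anyway: they are the standard construction for
MA rates, and they never undercover.

Two practical notes. The per-line analyzed-site count $N_i$ should come
from the sequencing pipeline (callable sites); when only a genome-wide
design is known, `rate_from_counts()` uses the full genome length for every
line, which shifts rate estimates by well under 1% for high-coverage data
but is the reason third-digit agreement with per-line-denominator results
is not expected. Insertions and deletions share the all-sites denominator
with substitutions; `estimate_rate(..., mclass = "indel")` simply restricts
the numerator.

## Bottleneck effective size

A daily single-colony transfer grows one cell into a colony over $g$
doublings (sizes $2^0, 2^1, \dots$). No formula for the effective size of
this regime is universally agreed; we adopt the harmonic mean of the
per-generation sizes,

$$N_e = \frac{g}{\sum_{i=0}^{\lceil g\rceil - 1} w_i\, 2^{-i}},$$

with a fractional last generation weighted by $g - \lfloor g\rfloor$. The
harmonic mean is the classical reduction for fluctuating population size,
and the geometric growth makes the sum converge to 2, so $N_e \to g/2$:
about 13.7 (rounding to 14) for $g = 27.48$. Values this small mean drift
overwhelms selection within MA lines, the design's purpose. This choice of
estimator is an assumption, recorded here because alternative definitions
(e.g. inbreeding vs variance effective size under growth) differ in detail.

## Site opportunities and mutation classification

Synonymous/nonsynonymous site counting is Nei–Gojobori-style and
fractional: each codon position contributes one site, apportioned by the
fraction of its three possible substitutions that are synonymous. The
fraction can be weighted by a six-class spectrum (`spectrum_weights`),
because a mutationally biased process "sees" sites differently; the default
is uniform over the twelve directed changes. The standard genetic code is
used; bacterial translation-table start-codon special cases are ignored for
synonymous/nonsynonymous calls, and changes into or out of stop codons
count as nonsynonymous. CDS features whose phase-adjusted length is not a
multiple of 3 are skipped with a warning rather than silently truncated.

Classification of a substitution is strand-aware (minus-strand genes
complement both alleles), and the six-class spectrum collapses
complementary changes, so the class never depends on which strand reported
the call. Positions inside two or more genes are labeled `overlap`: they
are excluded from the synonymous/nonsynonymous tallies (whose category
table keeps overlap as its own row) but attributed to *every* overlapping
gene for gene-level tests, where partial attribution would dilute signal.
Records whose stated reference allele disagrees with the genome are
flagged and reported, never dropped: they usually indicate an ancestor that
already differed from the reference assembly.

4-fold degenerate sites are third-codon positions whose three alternative
bases all encode the same amino acid; any mutation there is synonymous by
construction, making the 4-fold rate a selection-free check on the
genome-wide rate.

## Spectrum and neutrality tests

2x2 contingency comparisons (transitions vs transversions between groups;
insertions vs deletions) use the Pearson chi-square with the Yates
continuity correction by default, each $|O - E|$ shrunk by 0.5 and floored
at 0. The correction is the default because small MA count tables are
exactly the situation it was designed for; the uncorrected statistic is one
argument away. Ratios such as ts/tv are always computed from the count
table itself — when a published ratio and its count table disagree at the
second decimal, the counts win.

The neutrality check is a 1-df goodness-of-fit of observed
(nonsynonymous, synonymous) counts against $r : 1$, where $r$ is the
nonsynonymous-to-synonymous site-opportunity ratio. $r$ is treated as
fixed and known (it is computed from the genome, not estimated from the
events), which is what keeps the test at one degree of freedom. Whether to
weight $r$ by the observed spectrum is left to the caller: weighting is
more faithful to the mutation process but couples the expectation to the
data; the package supports both and defaults to uniform.

## Selection scans

**Hotspots.** Under rate homogeneity a gene of length $L_g$ in a genome of
$S$ analyzed sites expects $M L_g / S$ of the $M$ observed mutations. Genes
are scored by the Poisson upper tail of their observed count and
Bonferroni-corrected. The family size is the full annotation by default —
deterministic and conservative — with `family = "tested"` (genes with at
least one hit) available, since either reading of "Bonferroni over genes"
is defensible.

**Allele frequencies.** Population (polymorphism-mode) records carry
mutant allele frequencies; filtering is strictly greater-than the
detection threshold (default 5%), matching how polymorphism callers report
variants, and per-gene means average only observed variant sites —
frequency-zero sites are unobservable in that representation, a fact to
keep in mind when comparing genes with different site counts. Intergenic
variants are grouped under a nearest-gene pseudo-label
(`intergenic:<gene>`; ties go to the earlier gene).

**Ka/Ks.** Within-experiment event counts are sparse, so Ka and Ks are
plain event-per-site quotients with no multiple-hit (Jukes–Cantor)
correction. Genes with zero synonymous events would have an undefined
ratio; instead a pseudo-Ks is predicted from a least-squares regression of
synonymous count on synonymous sites, forced through the origin, across
genes with at least one synonymous event, with the predicted count floored
at half an event (0.5) so a tiny gene never gets a pseudo-Ks of zero.
These genes are flagged `calibrated`. The through-origin form is the
natural zero-intercept model (zero sites admit zero events); the floor is
this package's defined convention. If fewer than two genes have synonymous
events the regression is unfittable and the bare floor is used, with a
warning.

## Phenotypes

Efficiency of plating is the treated-to-control CFU ratio, reported as-is
even above 1. The MIC of a plating series is the lowest tested
concentration at which every replicate shows zero CFU — zero colonies
being the only machine-checkable proxy for "no visible growth" — and a
series that never reaches zero raises a typed `mic_above_range` condition
rather than guessing. Growth rates are slopes of log-density vs time; the
default fit window keeps points between 10% and 90% of the curve maximum
(the exponential phase), falling back to all points when fewer than three
qualify.

## Simulators

The simulators exist so every analysis stage has statistically honest
input at desk scale.

**MA generator.** Per line, the substitution count is Poisson with mean
`rate * N * T`; each event draws its class from the configured spectrum
and then a position uniformly among that class's origin-pair (A/T or G/C)
sites. Drawing the class first makes the realized class proportions
converge on the configured ones regardless of genome composition — the
property the analyses assume; drawing positions first would make the
realized spectrum composition-weighted. Mutations are clonal singletons
(no within-line polymorphism) and there is no multi-hit bookkeeping; a
guard refuses configurations whose expected per-line load exceeds 10% of
sites. Default parameters are the study design the package accompanies:
142 lines, 27.48 divisions per transfer, 40 transfers, substitution rate
1.45e-10, indel rate 1.94e-11, and the control spectrum. Tests and the
demo run use smaller genomes and boosted rates, chosen so each suite
finishes in seconds while keeping hundreds-to-thousands of events per
check.

**Serial-transfer Wright–Fisher.** Populations are simulated at a scaled
size (default $10^5$ cells at full growth, i.e. a bottleneck of ~100 under
the default 1:1000 dilution and 10 doublings per cycle) rather than the
~$10^{11}$ cells of a real flask: desk-scale drift fidelity, not census
realism, is the goal, and selection coefficients are interpreted at the
scaled size. Regrowth between transfers is deterministic (drift at the
1000-fold bottleneck dominates the noise), with haploid selection
$p' = p(1+s)^g / (p(1+s)^g + 1 - p)$ applied per cycle; the bottleneck
resamples each segregating site binomially — the site-wise marginal of
multinomial resampling under an unlinked-sites approximation. Linkage and
clonal interference are deliberately out of scope. New neutral mutations
enter at `mu` per site per division with arising times weighted by the
divisions per generation, so most arise late and start rare, as in a real
expansion. Designated resistance loci receive their own mutational supply
(`locus_mutation_rate`, expected new mutant cells per cycle, default 0.2):
resistance targets are many-site genes whose aggregate supply at census
scale is large, and this default makes establishment of a driver with
$s = 0.1$ over 40 cycles near-certain, consistent with resistance
mutations fixing in every parallel treated population in the motivating
design. With unlinked sites the wild type can never go extinct, so no
extinction handling is needed. The pure drift kernel is exposed as
`simulate_drift()` and is calibrated against the classical variance decay
$p(1-p)\,[1 - (1 - 1/N_e)^t]$ in the test suite.

**Plating.** Replicate CFU counts are Poisson at `eop * reference_cfu`;
zero-efficiency concentrations therefore give exactly zero counts and a
well-defined MIC.

What the simulators do *not* emulate: sequencing and alignment error,
coverage variation and callability masks, context-dependent (triplet)
mutation biases, rate variation along the chromosome, structural variants,
and within-line polymorphism. Passing tests therefore validate the
estimators and their statistical behavior, not robustness to upstream
calling artifacts.

## Numerical choices and degenerate inputs

- Coordinates are 1-based inclusive everywhere (VCF/GFF3 convention);
  multi-allelic VCF rows are split into independent records; indels are
  VCF-anchored and their length excludes the anchor base.
- N bases are excluded from all site-opportunity counts and never receive
  simulated mutations.
- Empty record sets are legal everywhere they can arise: rates are 0 with
  a 0 lower bound, spectra are all-zero, filters return empty tables.
- `poisson_ci()` insists on integer $m$; fractional counts indicate an
  upstream bookkeeping error rather than a statistical question.
- Ties in the nearest-gene label go to the earlier gene in the annotation;
  hotspot results are sorted by adjusted then raw p-value, then gene id,
  so output order is deterministic.
- All generators are bit-reproducible under a fixed seed, and a pipeline
  run is a pure function of (config, seed).

## Known limitations

Ka/Ks on sparse counts is noisy and the zero-synonymous calibration is a
convention, not an estimator with sampling theory; treat calibrated ratios
as screening values. The hotspot test assumes rate homogeneity, so genes
in genuinely mutagenic contexts can reach significance without selection.
The exact Poisson intervals' conservatism means simulated coverage sits
above the nominal level at small means; that is a property of the interval,
not a bug in the simulation. The Wright–Fisher model's unlinked-sites
approximation overstates the independence of co-segregating drivers in a
strictly asexual population.
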