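---
title: "Spatially explicit analysis of forensic STR surveys: models and methods"
author: "strscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatially explicit analysis of forensic STR surveys: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strscape)
```

## The problem

Forensic STR panels (here modelled on a 16-locus identification kit) were
designed to maximise diversity *between individuals*, which makes them poor
carriers of diversity *between populations*: across a few thousand
kilometres, the among-location fixation index Fst of such a panel is of the
order of 0.002. Yet surveys that keep many small, precisely georeferenced
location samples contain a real spatial signal — weak longitudinal clines
in a handful of allele frequencies, plus local highs and lows created by
drift and endogamy in geographically confined populations. `strscape`
implements the analysis chain that extracts this signal: spatial PCA over a
nearest-neighbour network, reduction of the allele panel to the strongest
spatial contributors, F-statistics on the reduced biallelic recodings, and
coalescent simulation to translate the observed Fst into bounds on
migration rates.

## Data model

An `STRDataset` holds diploid genotypes for every subject at every locus
(profiles with missing loci are assumed discarded upstream, mirroring
forensic QC), with each subject assigned to a georeferenced location
sample. Allele labels are repeat counts with one optional decimal
(microvariants such as 15.2); internally they are canonical integer tenths
(152), which round-trip losslessly.

Genepop files carry the genotypes; coordinates live in a sidecar CSV so
both formats stay standard. Genepop has no native decimal alleles, so the
package writes a documented dialect: each 3-digit code is the canonical
tenths form (allele 15 is `150`, allele 15.2 is `152`). Files from tools
that use plain repeat counts (`015` = allele 15) are read with
`dialect = "integer"`.

## The synthetic generator as the study system

Real forensic genotypes are confidential, so the package carries a
first-class generator (`syntheticSpec()`, `makeFrequencySurfaces()`,
`sampleGenotypes()`) whose defaults emulate the kind of survey the methods
target:

* **41 locations** on an elongated east-west transect (~28 degrees of
  longitude, ~5 of latitude), 38 diploids per location — the scale of a
  fine-grained Mediterranean survey (~1560 subjects).
* **16 loci, 288 alleles** in total, with allele counts from 9 (e.g.
  D10S1248, D16S539, TH01) to 65 (SE33); several loci carry x.2
  microvariants.
* **Eight longitudinal clines** on eight distinct many-allele loci. Clines
  are logistic in the eastward transect position with maximal slope 0.1
  frequency units per 1000 km and total swing 0.15, added to a baseline
  Dirichlet frequency vector shared by all locations and renormalised. The
  logistic form keeps frequencies in [0, 1] without renormalisation
  artefacts at the transect ends; alternating directions mimic clines of
  both orientations. With these defaults the whole-panel Weir-Cockerham
  Fst of a generated survey is ~0.0015-0.002, the order observed for real
  forensic panels at this scale.
* **Six local frequency foci** (single-location bumps of 0.08) standing in
  for drift/founder effects in confined locations.
* **Inbreeding** Fis = 0.012 per location, simulated per genotype: with
  probability Fis the two gene copies are one draw used twice
  (identical-by-descent), which yields the target Fis exactly in
  expectation rather than distorting frequencies.
* **Null alleles** (off by default): a hidden extra allele per locus;
  null/visible pairs are reported as visible homozygotes and null/null
  genotypes are resampled, because the data model — like the upstream QC it
  mirrors — has no missing genotypes.

Everything is a deterministic function of the spec, including its seed.

What the generator does *not* emulate: linkage between loci (forensic STRs
are effectively unlinked), sequence-level mutation structure, relatedness
between subjects, and genotyping artefacts other than null alleles. Tests
that pass on synthetic data therefore validate the *statistical machinery*
under the stated model, not robustness to every feature of real surveys.

## Classical statistics

**Weir-Cockerham theta.** Multi-allelic, multi-locus: per allele and locus
the variance components a (among groups), b (among individuals within
groups) and c (within individuals) are computed from the 1984 formulas and
theta is the ratio of sums, $\theta = \sum a / \sum(a+b+c)$. Monomorphic
loci contribute zero to every component; a dataset monomorphic everywhere
leaves theta undefined and raises an error rather than returning 0.
Significance uses permutation of subjects among groups with
$p = (1 + \#\{\theta_{perm} \ge \theta_{obs}\})/(B+1)$, which bounds p
below by $1/(B+1)$.

**Fis.** $1 - H_{obs}/H_{exp}$ per locus and location, with the
$2n/(2n-1)$ small-sample correction on expected heterozygosity.
Monomorphic cells are excluded from averages and counted.

**Hardy-Weinberg exact test.** The Guo-Thompson switch chain over genotype
tables with fixed allele counts. A proposal picks two individuals and
re-pairs their four alleles; the Metropolis ratio multiplies the
conditional-probability ratio ($2^{\Delta h}$ times exact factorial
ratios) by the selection-probability ratio. The p-value is the proportion
of retained states whose conditional probability does not exceed the
observed table's. The package default follows survey convention (10^6
retained steps after 10^5 burn-in); the tests use shorter chains checked
against exact enumeration over all tables with the observed margins.

**Null alleles.** An EM estimator on the visible-genotype likelihood: each
apparent homozygote count is apportioned between true homozygote and
visible/null carrier under the current frequencies, the truncated
null/null class enters as its conditional expectation
$N r^2/(1-r^2)$, and all frequencies (including r) are re-estimated by
gene counting. The observed-data log-likelihood is non-decreasing across
iterations; non-convergence within `maxIter` is flagged, returning the
last iterate.

## Spatial machinery

Distances are haversine great circles on a 6371-km sphere. The connection
network is k-nearest-neighbour (k = 12 by default at 41 locations, the
density that connects locations within and between regions of such a
transect), symmetrised **by union before row-standardisation** — an edge
survives if either endpoint lists the other — because the lag operator of
an undirected field should not depend on which endpoint ranked the
neighbour.

**Spatial PCA.** With X the column-centred locations-by-alleles frequency
matrix (centring only; allele frequencies share units, so no scaling) and
L the row-standardised network weights, the analysis eigen-decomposes
$H = X^\top (L + L^\top) X / (2n)$. Each component maximises
$\mathrm{var}(s)\cdot I(s)$ of its scores $s = Xv$, so positive
eigenvalues capture "global" structure (neighbours alike — clines) and
negative ones "local" structure (neighbours contrasted). The
implementation works in the n-dimensional dual — eigenvalues of
$G^{1/2} A G^{1/2}$ with $G = XX^\top$, $A = (L+L^\top)/(2n)$ — which is
exact, fast for p >> n, and leaves the dense p-by-p eigensolve available
as an independent oracle in the tests. The defining identity
$\lambda_k = \mathrm{var}(s_k) I(s_k)$ is asserted to 1e-8 for every
component. Row weights are uniform (location sample sizes do not weight
the analysis); the rank bound count(positive) + count(negative) <=
min(n-1, p) holds by construction.

**Global-structure test.** The network is held fixed while location rows
are permuted and the largest positive eigenvalue recomputed;
$p = (1+\#\{\lambda^{max}_{perm} \ge \lambda^{max}_{obs}\})/(B+1)$. This
row-permutation statistic is a documented surrogate for adegenet-style
global tests, whose exact construction varies between software
implementations.

**Correlograms.** Six distance classes by default (upper bounds 200, 400,
800, 1200, 1600, 3200 km — short classes within countries, long classes
between them). Within a class the weights are binary over the pairs of
that class (the PASSaGE convention, not row-standardised); significance is
a two-sided permutation test, Bonferroni-corrected by the number of
classes (capped at 1). A correlogram is flagged "clinal" when I decreases
monotonically over the classes. Coincident locations fall into the first
class so that the classes always partition all pairs.

**Mantel test.** Pearson correlation of the off-diagonal upper triangles,
one-tailed, permuting rows and columns of one matrix jointly; for n <= 7
all n! permutations are enumerated, making the p-value exact.

**Kriging.** Ordinary kriging with an exponential variogram fit to the
binned empirical variogram by weighted least squares (Cressie weights
$N_j/\gamma_{mod}^2$). The kriging system keeps the nugget on the
lag-zero diagonal *and* in the prediction covector at coincident points,
so the predictor returns the observed value at every sampling location
(asserted to 1e-6); the default grid is 200 x 200 spanning the sampled
extent. A singular system falls back to a logged diagonal jitter,
escalated from 1e-10. No geostatistics package in the dependency set
exposes this contract, so the ~70-line solver is part of the package.

## Reduced datasets

The distribution of squared loadings on each retained component ranks the
288 alleles; the top quantile q keeps $\lceil q\,p\rceil$ alleles (the
ceiling rule reproduces the canonical counts 4/8/15/22/29 at q = 1.25%,
2.5%, 5%, 7.5%, 10% on 288 alleles). Ties in squared loadings are broken
by locus/allele order and flagged. Each selected (locus, allele) becomes a
biallelic pseudo-locus scoring the dosage {0,1,2} of the target allele
against all remaining alleles of that locus; pseudo-locus frequencies
equal the source allele frequencies exactly, and downstream F-statistics
accept the recoded dataset directly.

Three diagnostics accompany a pair of selections: (a) alleles shared
between the two components' selections, (b) loci contributing more than
one allele within a selection (negative internal correlation), and (c)
whether each recoded dataset raises Fst above the full panel. (a) and (b)
are advisory — real analyses tolerate a few violations — while (c) is the
pass/fail criterion for "improved ability to detect structuring".

## Coalescent simulation

The simulator is discrete, generation-by-generation and backward in time,
with all population sizes in gene copies and all rates per lineage per
generation — fastsimcoal's conventions, under which exactness concerns
vanish for rates <= 0.02 and time-varying sizes are trivial.

**Model 1** (residents): 14 demes split from a pool of 100,000 current
gene copies that has been growing at 0.020/generation. Split times are
drawn per deme per replicate from UNIFORM(224, 276) generations; *founding*
sizes from UNIFORM(800, 2400) gene copies, growing at 0.017/generation
from the split to the present (~1.1e5 copies today for a median deme).
The uniform range is read as the founding rather than the present-day
size: a present-day size of ~1600 copies would imply a ~23-copy founding
bottleneck and an order of magnitude more differentiation than surveys
of this kind exhibit.
Demes exchange migrants among themselves at rate m (per-pair
$m/(n_{demes}-1)$, i.e. per-lineage total m, giving ~30 emigrant copies
per deme per generation at m = 0.02) and exchange gene copies with the
pool at 1e-3 (sending) and 1e-4 (receiving). Exchange rates of this kind
are conventionally quoted as forward flows; converting to the backward (lineage-tracing)
convention used by the engine, a deme lineage traces to the pool at the
immigrant fraction (1e-4) and a pool lineage traces to each deme at the
sending rate scaled by the deme/pool size ratio (~2e-5 per deme) — see
"Exchange-rate direction" below for how this choice was fixed.

**Model 2** (joiners): three additional demes split from the pool at 96,
96 and 18 generations ago (sizes and growth from the resident template)
and exchange migrants with the residents — and each other — at rate m2,
parameterised per pair as $m2/(n_{res}-1)$ so that m2 = m makes the
17-deme migration matrix uniform.

**Within-generation order**: splits (demes merging into the pool), then
migration, then coalescence by Wright-Fisher parent sampling — every
lineage draws a parent slot among the N(t) copies of its population, and
lineages sharing a slot merge (exact multi-mergers). Emigrant counts per
lineage class are drawn from the exact binomial and the emigrants picked
by partial Fisher-Yates, which preserves the per-lineage law while doing
O(events) work.

**Mutation**: stepwise (+/-1 repeat), K = 20 allele states by default with
reflecting bounds, mu = 5e-4 per locus per generation, 8 loci per
replicate (matching a reduced dataset's size); these constants are
conventions of the template, exposed as `mutationModel()` arguments. The free (unbounded) walk is simulated down the genealogy and
folded into [1, K] at the tips by the billiard map of period 2(K-1) —
pathwise identical to reflecting each step, with a boundary state always
stepping inward.

**Validation**: on the constant-size island model the engine's mean Fst
matches the closed form $1/(1+4Nm(d/(d-1))^2)$ within a few percent at
Nm = 1 and Nm = 5 (test tolerance 25%, dominated by stepwise-mutation
homoplasy and finite sampling), and during development it was also checked
against an independent coalescent engine under identical settings. Fixed
seeds reproduce Fst vectors bit-exactly.

**Exchange-rate direction.** Quoted sending/receiving rates can describe
forward flows (to be converted) or backward lineage-tracing
probabilities, and the two readings differ markedly in how strongly the
pool homogenises the demes. The forward reading is adopted: it is the
natural reading of "demes send at 1e-3 and receive at 1e-4", and under
it the joiner-deme sweep behaves as the model family intends (complete
isolation distinguishable from weak exchange; a weakly connected joiner
set clearly more differentiated than a uniformly connected one), whereas
the backward-as-written reading drains so many deme lineages into the
pool that the joiner sweep loses its resolution. The converted backward
rates (deme to pool 1e-4, pool to each deme ~2e-5) are therefore the
defaults; any other pair can be supplied through `model1Demography()`'s
arguments.

**Sweeps.** `fstDistribution()` simulates R replicates at one rate (2000
by default; the acceptance checks scale to 500-1000), scores an observed Fst by empirical tail probabilities with the
$(1+k)/(R+1)$ convention, and `sweepMigration()` tabulates a rate grid,
marking rates "acceptable" at two-sided p >= 0.05 and "best fitting" by
closest simulated median. Default sample sizes are 30 diploids per deme,
the scale of the location samples such surveys collect.

## Problem sizes in the tests

The shipped tests exercise every operation at sizes chosen to keep the
whole suite inside a half-hour single-core run while leaving each check
statistically meaningful: recovery runs use 5-15 locations (500 diploids
per location where a +/-0.02 tolerance on Fis demands it), chain/exact
comparisons use tables of 10-16 diploids, coalescent property tests use
40-150 replicates, and the two model sweeps run at R = 500 (scaled from
the 2000-replicate default; the Monte-Carlo error of a median at R = 500 is well
inside the grid spacing). Calibration checks (permutation-p uniformity,
correlogram quiescence) use dozens of seeds and assert majority behaviour
rather than per-seed certainty.

## Known limitations

* The global-structure test is a row-permutation surrogate, not a
  re-implementation of any particular software's test statistic.
* The EM null-allele model assumes a single null allele per locus and
  Hardy-Weinberg within locations; Fis and null-allele frequency are
  confounded by design (the two estimates co-vary on purpose, as the
  diagnostics expect).
* Kriging assumes second-order stationarity with an exponential
  variogram; frequencies outside the sampled polygon are extrapolations.
* The coalescent engine covers the split-from-pool template family
  (including its island-model degenerate case), not arbitrary
  demographies.
* Mutation-model constants (mu, K, loci count) for the simulation are
  conventions, not measurements; conclusions that depend on them should be
  swept.
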