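---
title: "Models and methods behind riverpopgen"
author: "riverpopgen authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind riverpopgen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riverpopgen)
```

# The problem the package addresses

River-dwelling mammals such as the Bolivian river dolphin live in
branching channel networks where females are strongly philopatric and
males move widely. Population structure in such systems is usually
studied with two marker sets at once: a fast-evolving, maternally
inherited mitochondrial control-region fragment (here modelled as 400
aligned sites) and a panel of nuclear dinucleotide microsatellites.
`riverpopgen` implements the complete statistical toolbox such a study
needs — diversity, neutrality, differentiation, spatial pattern,
microsatellite demographic-change tests and network dating — together
with a structured-coalescent generator of synthetic river
metapopulations, so the whole pipeline can be exercised and calibrated
without any external data.

# Sequence statistics

## Diversity

For an alignment of $n$ sequences, `diversityStats()` reports the
haplotype count $H$, haplotype diversity
$H_d = \frac{n}{n-1}(1 - \sum_i p_i^2)$, the mean pairwise difference
$\bar k$, nucleotide diversity $\pi = \bar k / L$, segregating sites $S$
and Watterson's $\theta_{seq} = S / a_1$ with $a_1 = \sum_{i<n} 1/i$,
each with its classical sampling standard deviation. Sites containing a
gap or an N in any sequence are removed before anything is computed
(complete deletion), so $S$, $\pi$ and haplotype identity always refer
to one coherent site set; distances for tree/network building use the
same convention.

## Neutrality and demographic change

`neutralityTests()` computes Tajima's $D$, Fu and Li's $D^*$ and $F^*$
(folded versions, no outgroup), Fu's $F_S$ and the $R_2$ statistic.
$F_S$ needs the Ewens sampling probability of observing at least the
observed number of haplotypes at $\theta = \bar k$; the unsigned
Stirling numbers of the first kind in that distribution are evaluated
in log space through their row recurrence, which keeps the computation
stable at sample sizes in the hundreds.

Significance comes from simulating the constant-size neutral coalescent
conditioned on the sample size with $\theta = \bar k$ (the mean
pairwise difference), recomputing all five statistics per replicate.
$D$, $D^*$ and $F^*$ are tested two-tailed; $F_S$ and $R_2$ one-tailed
towards their expansion-sensitive low tail. Conditioning on $\bar k$
rather than on $S$ is a deliberate choice: it matches the moment the
statistics contrast and makes the null self-consistent for all five at
once. Because observed statistic and null distribution share one code
path, the tests hold their nominal size by construction; the test suite
verifies a type-I error between 2% and 9% at nominal 5%.

Samples of fewer than four sequences are flagged as degenerate rather
than scored: $D$ is identically zero at $n = 2$ and the $D^*/F^*$
variance constants are undefined below $n = 4$.

`mismatchDistribution()` fits the sudden-expansion model to the
pairwise-difference histogram. The expected frequencies are evaluated
exactly as incomplete-gamma mixtures over the two epochs
($\theta_1$ recent, $\theta_0$ ancient, transition at mutational time
$\tau$), fitted by least squares on log-transformed parameters
(Nelder-Mead, 2000 iterations, initial values $\tau = \bar k$,
$\theta_0 = 0.1$, $\theta_1 = 10\bar k$). Harpending's raggedness is
$rg = \sum (x_{i+1} - x_i)^2$ over the relative frequencies with a
trailing zero class. $p$-values for the squared deviation and for $rg$
come from a parametric bootstrap: coalescent samples are simulated
under the fitted two-epoch history and refitted each time.

# Sequence differentiation

`hudsonHeterogeneity()` computes the permutation-tested family
$H_{ST}$, $K_{ST}$, $K_{ST}^*$, $Z_S$, $Z_S^*$ and $S_{nn}$ together
with the fixation-type indices $\gamma_{ST}$, $N_{ST}$ and $F_{ST}$:

* $K_{ST} = 1 - K_S/K_T$ with $K_S$ the population-size-weighted mean
  within-population pairwise difference; the starred variant applies
  $\log(1+d)$ to all distances first.
* $H_{ST}$ has the same structure on unbiased haplotype
  heterozygosities.
* $Z_S$ is the size-weighted mean rank of within-population distances
  among all pairwise distances (ties share average ranks); $Z_S^*$
  averages log-ranks. Small values indicate structure, so these two are
  tested in the lower tail.
* $S_{nn}$ is the mean fraction of nearest neighbours belonging to the
  same population, ties sharing weight equally.
* $\gamma_{ST}$ uses harmonic-mean sample-size corrections on haplotype
  frequencies; $N_{ST}$ applies the same unweighted-population
  construction to mean pairwise sequence differences; $F_{ST}$ is the
  pooled $1 - \bar d_{within}/\bar d_{between}$ estimator.

All permutation $p$-values in the package are
$(\text{exceedances}+1)/(B+1)$ and therefore never exactly zero.
Gene-flow conversions use the infinite-island relations
$Nm = (1-F)/(2F)$ for the haploid organelle marker and $(1-F)/(4F)$ for
diploid nuclear markers.

Exact tests on haplotype-by-population tables use full enumeration over
fixed margins when the table space is small and otherwise a Metropolis
chain whose proposal moves one unit around a random 2x2 subtable; the
chain runs the classical dememorisation/batch schedule (defaults
10,000 / 20 / 5,000) and reports the batch-mean standard error. The
AMOVA treats pairwise nucleotide differences as squared distances and
decomposes them into among-group, among-population-within-group and
within-population components with the standard nested sums of squares;
$\Phi$ statistics are tested by permuting individuals across the whole
sample ($\Phi_{ST}$), individuals within groups ($\Phi_{SC}$) and whole
populations among groups ($\Phi_{CT}$).

Kimura two-parameter distances are delegated to `ape::dist.dna`
(pairwise deletion); saturated pairs are flagged as missing, never
clamped. Net distances subtract the mean within-population distances.

# Microsatellite structure

Expected heterozygosity uses the unbiased
$\hat H_e = \frac{2n}{2n-1}(1 - \sum p_i^2)$. Exact Hardy-Weinberg
tests condition on allele counts: biallelic tables are enumerated over
the parity-constrained heterozygote count, larger tables run a chain
that repeatedly picks two individuals and re-pairs their four gene
copies — on the space of matchings of gene copies this proposal is
symmetric and every move is accepted, so the chain samples the exact
conditional null. Robertson-Hill's $f$ is
$(\sum_i P_{ii}/p_i - 1)/(k-1)$. Fisher's combination across loci or
populations uses $\chi^2 = -2\sum \ln p$ with degrees of freedom equal
to twice the number of combined tests.

Wright's F-statistics use the Weir-Cockerham variance components
(equivalently the AMOVA-based formulation), with per-allele components
summed within loci and across loci for multilocus values; negative
component estimates are retained so the multilocus sums stay unbiased.
Significance of overall differentiation randomises multilocus genotypes
among populations and compares log-likelihood $G$ statistics summed
over loci. Nei's (1978) unbiased distance applies the
$(2n J - 1)/(2n - 1)$ small-sample correction to the within-population
gene identities and averages identities across loci before taking the
log.

The private-allele gene-flow estimate maps the mean private-allele
frequency through the published log-linear regressions for reference
sample sizes 10, 25 and 50 (the nearest size is used, with the usual
$n_{ref}/\bar n$ correction). Assignment supports the frequency
criterion (unobserved alleles at a substitute frequency of 0.01 so
likelihoods stay finite; configurable), a Bayesian criterion using
posterior-predictive allele frequencies $(x_i + 1/k)/(2n + 1)$, and two
genetic-distance criteria. Exclusion probabilities and the
first-generation-migrant test on $L = L_{home}/L_{max}$ use Monte-Carlo
genotypes drawn from each candidate population's frequencies; an
individual is flagged when its observed ratio falls below the
$\alpha$ quantile of the simulated resident null.

# Microsatellite demography

Four tests of demographic change operate on allele sizes in repeat
units (the container converts from base pairs at I/O time):

**Imbalance index.** $\theta_V = 2V$ from the allele-size variance and
$\theta_{P_0}$ from inverting the single-step equilibrium relation
$P_0 = 1/\sqrt{1+2\theta}$. The multilocus ratio
$\beta = \theta_V/\theta_{P_0}$ exceeds 1 after a
bottleneck-then-expansion history. The multilocus value averages $V$
and $P_0$ over loci *before* inverting: the inversion is convex, and
transforming per-locus values first biases $\ln\beta$ visibly downward
at realistic loci counts (about $-0.33$ at 10 loci and $\theta = 5$ in
our calibration runs, against $-0.06$ for the implemented form).
Significance by delete-one-locus jackknife and Student's $t$ with
(loci - 1) df.

**Expansion index.** $S_k = 1 - (K - R_k V/2)/(5V^2)$ with $V$ and $K$
the bias-corrected variance and fourth central moment of allele size
averaged over loci and $R_k$ the mutational kurtosis/variance ratio
(default 6.3 for dinucleotide repeats; the step-size variance 2.39 is
carried in the result for reference). The denominator uses the unbiased
estimate of $(E V)^2$, namely $\bar V^2 - s^2_V/L$; the plain $\bar
V^2$ inflates $S_k$ at small loci counts for the mirror-image reason.
$S_k$ is near zero at equilibrium, positive under expansion, negative
after a bottleneck. Note the printed form of this statistic circulates
with unbalanced parentheses; the implemented reading is the only one
with this sign behaviour and zero equilibrium expectation.

**M ratio.** $M = k/r$ per locus with $k$ distinct alleles and
$r = \max - \min + 1$ the inclusive allelic range, so alleles two
repeats apart give $M = 2/3$. The equilibrium null
(`gwNullDistribution()`) simulates single-locus coalescents under the
two-phase model: with probability $p_s$ a mutation moves one repeat,
otherwise $2 + \text{Geometric}$ repeats with overall mean $\Delta_g$
(multi-step mutations are at least two repeats — with plain
geometric-$\ge 1$ steps the simulated critical values are visibly too
low against published reference values). Each replicate averages M over
`n_loci` loci so that the 5th-percentile critical value $M_c$ refers to
the same quantity as an observed multi-marker mean; `n_loci = 1` gives
the single-locus distribution. A population is called reduced when
fewer than 5% of equilibrium replicates fall below the observed value.

**Intralocus and interlocus tests.** The intralocus test scores the
sign of the bias-corrected excess kurtosis of allele length per
polymorphic locus and evaluates the one-tailed binomial probability of
at most the observed number of positive loci, each positive with
probability 0.515 under constant size. Only the sign of the per-locus
statistic enters, which insulates the binomial $p$ from the choice of
kurtosis correction. The interlocus statistic is
$g = s^2_V / \left(\tfrac{4}{3}\bar V^2\right)$ — the variance of
per-locus allele-size variances scaled by its approximate constant-size
expectation, so $g \approx 1$ at equilibrium — and its 5th-percentile
cutoff is simulated from a constant-size coalescent matched to the loci
count, sample size and $\theta = 2\bar V$. Because the null is matched
simulation, the normalization constant cancels out of the decision.

# Spatial structure

The normalized Mantel statistic is the Pearson correlation of the
off-diagonal halves of the genetic and geographic matrices, with joint
row/column permutations; a log-distance variant serves isolation-by-
distance testing along rivers. Distance classes default to
equal-pair-count (quantile) boundaries over the observed pair
distances, with a fixed-width override; pairs fall into half-open
intervals, the last class closed.

The distance-class correlogram statistic is the mean normalized genetic
distance among pairs in a class — exactly 0 when all members are
identical, exactly 1 when all pairs are maximally distinct (the genetic
matrix is normalized by its maximum to guarantee the interpretation) —
with an overall variance-across-classes statistic. The molecular
autocorrelation (`aidaAutocorrelation()`) codes every allele at every
segregating site as an indicator over individuals, pools numerators and
denominators across indicators, and computes Moran-type $II$ and
Geary-type $cc$ per weight set; weights come either from distance
classes or from a site-connectivity network (Gabriel graph, or
brute-force Delaunay triangulation adequate for the handful of sites in
a river basin; same-site pairs count as connected). Per-class
significance is Bonferroni-corrected at $\alpha/\text{classes}$.
Distograms use Gregorius' $d = \frac{1}{2}\sum|p_i - q_i|$ or the
shared-haplotype proportion (intersection over union of the two
haplotype sets), against a Monte-Carlo envelope from randomised
population locations. Genetic landscapes place each connectivity-edge
midpoint at the mean coordinate of its sites and interpolate a
50x50 grid by inverse-distance weighting with exponent $a = 1$
(defaults; all configurable), with exact hits returned verbatim.

# Networks and dating

The median-joining construction iterates: build the
minimum-spanning-network (all minimal alternative connections, relaxed
by $\varepsilon$, default 0); for every triple joined through a common
neighbour compute the position-wise majority consensus; add the
minimal-cost new medians whose Steiner cost undercuts the triple's
present connection cost (lexicographic order for determinism); finally
prune unsampled nodes of degree two or less, reconnecting their
neighbours. `networkCost()` reports the parsimony cost — the cheapest
subtree of the network connecting all sampled haplotypes — which never
exceeds the sampled-haplotype MST cost and matches brute-force Steiner
minima on small cases in the test suite.

Dating uses the rho statistic: the count-weighted mean mutational-step
distance from a user-designated root (root choice is explicit; no
automatic outgroup inference), with
$\sigma_\rho^2 = \sum_b n_b^2 l_b / n^2$ over the branches of the
shortest-path tree. The default conversion of one mutation to years,
166,667, is $1/(400 \times 1.5\times 10^{-8})$ — a 400-site fragment at
1.5% per million years; any other figure (for instance the slightly
different value circulating in the cetacean literature) can be passed
explicitly, and dates scale exactly linearly with it.

# The synthetic river metapopulation

The generator is an event-driven structured coalescent over the demes
of a river network, with piecewise-constant demographic histories
(constant, bottleneck, expansion). The migration convention is the
classical island pool: each lineage emigrates at per-generation rate
$m$ into a pool redistributed uniformly over all candidate demes
including its source (candidates are all demes in island mode, the
network neighbours in river mode), so the effective move rate is
$m(d-1)/d$ and the equilibrium expectations $F_{ST} = 1/(1+2Nm)$
(haploid) and $1/(1+4Nm)$ (diploid) hold for two demes. Sex-biased
dispersal is mechanistic: the maternal marker coalesces in the female
population ($N_f$ per deme) and migrates at the female rate $m_f$;
autosomal microsatellites use $2N$ gene copies and the sex-averaged
rate $(m_f + m_m)/2$. Sequences mutate under a finite-sites model with
transition bias (default ts/tv 10, control-region-like);
microsatellites under the same two-phase model as the M-ratio null,
with a reflective floor at one repeat.

`studyLikeFixture()` instantiates the sampling design of the
motivating study: ten sites at their published coordinates with
sequence sample sizes 36, 10, 3, 5, 3, 5, 2, 2, 2 and 14 (82 animals)
on a nine-edge river network, and 61 genotyped animals across eight
sites (the two smallest sequence-only sites merged into their river
neighbours, since the study genotyped fewer sites than it sequenced).
Defaults were fixed once to magnitudes a field population geneticist
would call realistic for this system and then left alone: female deme
size 1500 with $m_f = 10^{-3}$ (philopatry; mitochondrial $F_{ST}$
around 0.2-0.4), diploid deme size 2500 with $m_m = 0.05$ (male-mediated
nuclear gene flow; microsatellite $F_{ST}$ near 0.01), a mitochondrial
rate of $1.5\times10^{-8}$/site/year with a 7-year generation (giving
$\pi \approx 0.005$ and haplotype diversity near 0.6), and a
microsatellite rate of $1.5\times10^{-5}$/generation (4-5 alleles per
locus, $H_e$ around 0.45, mean M-ratio near 0.8), history constant.
The fixture reproduces the study's qualitative signature — maternal
differentiation far exceeding nuclear differentiation — in essentially
every seed, and that contrast is asserted in the test suite.

What the generator deliberately does not emulate: selection,
recombination, genotyping error and null alleles, uneven per-locus
mutation rates, and within-site kin structure. Tests passing on this
generator therefore validate the statistical machinery and its
calibration under the stated models, not robustness of the pipeline to
those real-data complications.

# Numerical and design choices worth knowing

* Permutation/Monte-Carlo $p$-values are always
  $(\text{exceed}+1)/(B+1)$; chains and simulations are seeded, and
  every pipeline stage derives its seed deterministically from the
  master seed plus the stage name, so reruns are byte-identical.
* Problem sizes in the shipped test-suite calibrations (for example 150
  neutral datasets with 200 null replicates each, 100 two-deme
  replicates for the $F_{ST}$ recovery, 10,000 replicates for the
  M-ratio null) were chosen to keep Monte-Carlo error comfortably
  inside the asserted bands.
* Saturated Kimura-2P pairs, monomorphic loci, single-individual
  populations, undefined statistics at $S = 0$ and all-missing
  individuals are flagged explicitly rather than silently dropped or
  clamped.
* The two cited marker panels of the motivating system number their
  sites differently; the package uses one canonical site labelling for
  both markers (the fixture's mitochondrial popmap has ten sites, the
  microsatellite popmap eight, with shared labels).
* The interlocus variance test ships only with the matched simulated
  null; a tabulated-cutoff mode would require the original published
  lookup table, which the package does not reproduce.
* The pipeline's command-line entry point is a thin wrapper
  (`inst/scripts/run-pipeline.R`) over `pipelineConfig()` +
  `runPipeline()`; the R functions are the primary interface.

# Known limitations

The exact-test chains report batch-mean standard errors but no formal
convergence diagnostics; very sparse tables deserve larger schedules.
The assignment module's migrant test uses leave-one-out frequencies for
the focal individual but full-sample frequencies for its simulated
null, which is anticonservative for very small home samples. The
Delaunay construction is planar in lon/lat and intended for the small
spatial extents of a single river basin. AMOVA assumes the
pairwise-difference matrix is Euclidean-embeddable enough for the
variance decomposition, the standard assumption of distance-based
molecular variance analysis.
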