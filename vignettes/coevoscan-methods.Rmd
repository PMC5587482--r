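---
title: "Detecting coevolving loci from interspecific allele-frequency correlations"
author: "coevoscan authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting coevolving loci from interspecific allele-frequency correlations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coevoscan)
```

## The problem

When a parasite is locally adapted to its host — parasites infect sympatric
hosts at a higher rate than allopatric ones — that pattern must be generated
by spatial covariation between the frequencies of the genes that determine
infection in the two species. `coevoscan` turns this observation into a
screening method: given per-population allele frequencies for a host and a
parasite sampled from the same N populations, it scans all host × parasite
locus pairs for spatial correlations and flags pairs whose correlation is
too large to be explained by independent drift. The package also contains
everything needed to study the operating characteristics of that screen:
an individual-based coevolution simulator, a simulated reciprocal
cross-infection experiment, and a replicate harness that measures power and
type I error as functions of the strength of local adaptation.

## The statistic

Local adaptation is measured from an N × N cross-infection matrix $P$,
whose entry $P_{ij}$ is the expected infection rate of parasites from
population $i$ on hosts from population $j$:

$$L = \overline{\operatorname{diag}(P)} - \bar P,$$

the mean infection rate on sympatric hosts minus the grand mean. (The
normalization by N keeps $L$ on the scale of the published empirical
estimates, roughly 0.05–0.25, and independent of the number of populations;
the sums alone would grow with N.) $L$ admits an exact decomposition over
multilocus genotypes at the loci that determine infection:

$$L = \sum_{i}\sum_{j} \alpha_{ij}\, \operatorname{Cov}(X_i, Y_j),$$

where $\alpha_{ij}$ is the infection rate of parasite genotype $i$ on host
genotype $j$ and the covariance is taken across populations between the
parasite genotype frequency $X_i$ and the host genotype frequency $Y_j$,
using the population normalization (divide by N). `local_adaptation()` and
`local_adaptation_via_covariance()` implement the two sides; on an exact
cross-infection matrix they agree to numerical precision, and the test
suite enforces agreement at $10^{-10}$ across both infection models and 1–3
coevolving loci. This identity is why the screen works: nonzero $L$ forces
nonzero interspecific covariances at the functional loci.

The screen itself computes, for every host locus $i$ and parasite locus
$j$, the spatial correlation $\rho_{ij}$ of their allele frequencies across
the N populations and refers

$$t_{ij} = \rho_{ij} \sqrt{\frac{N-2}{1-\rho_{ij}^2}}$$

to a Student's t-distribution with $N-2$ degrees of freedom. The test is
two-tailed by default: 0/1 allele labels are arbitrary, so the sign of a
correlation carries no information (relabeling an allele flips the sign and
leaves $|t|$ unchanged — a property the tests check). No multiple-testing
correction is applied; the screen is deliberately run at raw $\alpha$ and
its false-positive behaviour is studied as a function of $L$.

Monomorphic loci (zero spatial variance) have no defined correlation. They
are reported as `NA`, are never significant, and stay in the denominator of
the type I error rate, which divides by the *total possible* number of
false positives ($n_H n_P$ minus the number of functional pairs). The type
II rate divides by the number of functional pairs, and "detection" of a
multi-locus architecture requires *every* functional pair to be
significant — partial identification counts as failure.

## The simulator

`run_simulation()` follows haploid hosts and parasites through a
four-stage life cycle — (1) species interactions, (2) reproduction,
(3) mutation, (4) migration — in a linear array of N demes. Genomes are 100
diallelic loci per species by default, of which a random subset of 1–3
per species (the coevolving loci) determines infection; the remainder are
neutral markers that drift, migrate and hitchhike, providing the
false-positive substrate for the scan.

Two infection models are provided. Under **discrete matching**, the
infection probability of an encounter is $1-\beta M$ with $M$ the fraction
of positionally paired coevolving loci whose alleles differ; at $\beta = 1$
it is the classical matching-alleles model. Coevolving loci are compared
positionally (host locus $k$ with parasite locus $k$ in the order drawn),
so the functional truth set is those index pairs. Under **quantitative
matching**, each individual's phenotype is the fraction of "1" alleles at
its coevolving loci and infection probability is
$\exp(-\beta\,\delta^2)$ with $\delta$ the host–parasite phenotype
difference. Those loci contribute additively and are interchangeable, so
every coevolving host locus is functionally coupled to every coevolving
parasite locus (the truth set is the cross product) — which is also why
power erodes faster with locus number under this model: local adaptation
can be carried by a subset of the pairs.

Each host meets exactly one parasite drawn uniformly with replacement from
its deme (and each parasite one host); survival is a Bernoulli draw on
$W_h = 1 - sP$ for hosts and $W_p = P$ for parasites. Survivors mate in
random pairs (drawn with replacement) to restore the census size $\eta$;
gametes start on a random parent and recombine between adjacent loci $i$,
$i+1$ with rate $r_i$. Each offspring genome then mutates with genome-wide
probability $\mu$ (exactly one uniformly chosen locus flips). Migration is
a linear stepping stone realized as symmetric swaps: each adjacent deme
pair is visited once, left to right, each individual of the left deme
initiates an exchange with probability $m/2$ with a uniform partner from
the right deme. Deme sizes are exactly conserved and the two terminal
demes, having one neighbour, experience half the interior migration rate.

Choices the underlying description leaves open, and what we chose:

* **Initial conditions** — every allele is drawn "1" with probability 0.5,
  symmetric and uninformative; there is no burn-in. Sensitivity is expected
  to be weak after 500 generations but has not been exhaustively mapped.
* **Encounter draws** — each individual of each species draws its own
  partner independently (with replacement), so unequal $\eta_H \neq \eta_P$
  poses no bookkeeping problem and every parasite receives a fitness draw.
  Parasites encountered by several hosts draw independently.
* **Extinction guard** — if selection leaves fewer than two survivors in a
  deme, parents are drawn from the pre-selection deme instead; full
  mortality is vanishingly rare under the study ranges but must not fail
  silently.
* **Mutation is per-genome**, as worded in the source description of the
  process: at most one locus flips per genome per generation.

The generation loop runs in compiled code (Rcpp) — a full-scale replicate
(40 demes × two species × ~225 individuals × 100 loci × 500 generations)
draws on the order of $10^9$ uniforms, nearly all of them for the
per-interval recombination switches. The engine uses an internal
xoshiro256++ stream re-seeded from R's RNG at every entry point, so
`set.seed()` (or `sim_params(seed = )`) makes runs bit-identical while
keeping the per-draw cost low.

## Parameters

Defaults of `parameter_ranges()` are the uniform study ranges (values drawn
once per replicate):

| parameter | meaning | range |
|---|---|---|
| $n_H, n_P$ | loci per genome | fixed, 100 |
| $m_H, m_P$ | per-individual migration probability | U[0, 0.01] |
| $\beta$ | infection sensitivity | U[0.8, 1.0] discrete; U[2.0, 4.0] quantitative |
| $s$ | virulence (host fitness cost of infection) | U[0.6, 0.9] |
| $\eta_H, \eta_P$ | deme census size | U[150, 300] |
| $\mu_H, \mu_P$ | genome-wide mutation probability | U[0.01, 0.05] |
| $r_{i,i+1}$ | adjacent-locus recombination rate | U[0, 0.5] per interval |
| generations | life cycles per replicate | fixed, 500 |

## Conditioning on the strength of local adaptation

The harness (`accumulate_bins()`) draws parameters, runs replicates, and
retains them until every requested bin of $L$ — minimal ($L \le 0.10$),
weak ($0.10 < L \le 0.15$), moderate ($0.15 < L \le 0.20$), strong
($L > 0.20$) — holds the requested number of records. All summaries
(`power_table()`, `type1_vs_L()`) condition on the *realized* bin.

Strong parasite local adaptation is a tail event under the unbiased
ranges. In these dynamics (and in metapopulation coevolution theory
generally) neither species is locally adapted on average when the two
species have symmetric migration, mutation and census sizes: demes then
alternate between matched and mismatched phases and the snapshot covariance
averages near zero. Parasite local adaptation emerges when the parasite's
evolutionary potential exceeds the host's — in particular when parasite
gene flow feeds adaptive variants into demes faster than host gene flow
does. The conditional studies therefore accelerate strong-bin filling by
biasing the migration draws (host movement in [0, 0.0005], parasite
movement in [0.006, 0.01]) while leaving every other range at its default.
Because power and error rates are analysed conditional on the realized
$L$ bin, the biased prior changes how often bins fill, not what is measured
within them. The long-running unbiased protocol is
`scripts/reproduce_power.R`.

## The synthetic generator

`synth_correlated_frequencies()` makes the scan testable without the
simulator: it plants host–parasite locus pairs with a chosen correlation
$\rho_{\text{true}}$ via a bivariate Gaussian on the logit scale mapped
through the inverse logit (a Gaussian copula), leaving all other columns
independent logit-normal noise. This keeps frequencies strictly inside
(0, 1), makes the planted correlation interpretable (the rank correlation
is preserved exactly; the Pearson correlation is mildly attenuated at the
default `sd_logit = 1`), and makes Fisher-z tail bounds available as an
independent oracle for tests. What it deliberately does **not** emulate:
spatial autocorrelation from stepping-stone gene flow, drift-induced heavy
tails near fixation, linkage between columns, or shared demographic
history — precisely the violations the simulator supplies. Null calibration
established on synthetic tables therefore shows the test is correct under
independence, not that it is robust to population structure; the
simulation study quantifies the latter and shows the type I rate is
inflated at weak $L$ and falls toward $\alpha$ as $L$ grows.

## Numerical choices and degenerate inputs

* Covariances and standard deviations use the population normalization
  (divide by N) so the scan's internals agree exactly with the covariance
  decomposition of $L$; the choice cancels in $\rho$ and therefore in every
  significance call.
* Correlations of exactly ±1 yield infinite $t$ and are significant at any
  level; floating-point overshoot beyond ±1 is clamped.
* $L$ values within $10^{-9}$ of a bin boundary are snapped to it, so
  printed-precision arithmetic (e.g. $0.80 - 0.65$) lands in the closed
  right end of its interval. $L \le 0$ is binned "minimal".
* Frequency tables must cover at least 3 populations for any correlation
  to be testable; readers reject out-of-range values naming the offending
  locus and deme.
* `accumulate_bins()` caps its draw budget and warns (returning partial
  results) rather than looping unboundedly when a bin cannot fill.

## Problem sizes used by the test suite

The suite exercises the identity, calibration and invariance properties on
miniature configurations (6–8 demes, 15–30 loci, 25–50 generations, deme
sizes 20–60) where thousands of replicates are cheap, and the power and
type-I acceptance checks on full-scale conditions (40 demes, 100 loci per
species, 500 generations) at reduced replicate counts: at least 10
strong-bin replicates for the near-certain-detection check and at least 6
moderate-bin replicates per model with exact-binomial acceptance regions
around the reference detection rates (93.3% discrete, 80.0% quantitative).
`scripts/reproduce_power.R` documents the full protocol (≥ 30 replicates
per bin under unbiased ranges) for readers who want the complete tables.

## Known limitations

* The t-based screen assumes independent populations and loci; with gene
  flow the degrees of freedom are overstated and the type I rate is
  inflated, increasingly so as local adaptation weakens. The method is
  meant to be applied only where strong local adaptation has been
  demonstrated experimentally.
* No population-structure correction (demographic null distributions,
  covariance-structure corrections) is implemented; that is future work.
* Haploid genetics only; diploidy, selfing, overlapping generations and
  two-dimensional stepping stones are out of scope, as are arms-race /
  escalation trait models, which do not produce the local-adaptation
  signal this screen relies on.
* Census allele frequencies are used by default; finite-sample estimation
  noise can be emulated upstream but is not modelled internally.
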