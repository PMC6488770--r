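---
title: "Relatedness and inbreeding from genotype likelihoods: the model behind relateGL"
author: "relateGL maintainers"
output: rmarkdown::html_document
vignette: >
  %\VignetteIndexEntry{Relatedness and inbreeding from genotype likelihoods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(relateGL)
```

## The problem

For two diploid individuals there are nine condensed identity-by-descent
(IBD) configurations of their four gene copies — the condensed Jacquard
states.  Their genome-wide frequencies `J1..J9` summarise the pair's shared
ancestry completely: relatedness, kinship, both inbreeding coefficients and
several other classical quantities are linear combinations of them.  With
deeply sequenced samples one can call genotypes and estimate these
coefficients from genotype counts; with low-coverage sequencing, genotype
calls are unreliable, and hard-calling biases the estimates.  relateGL
instead works directly with per-site genotype likelihoods
\(P(D \mid G = 0, 1, 2)\), integrating over the unobserved genotypes, so
sequencing uncertainty propagates into the estimate instead of being
ignored.

## The likelihood

For `L` unlinked biallelic sites with known population allele frequencies
\(f_l\) (of the allele counted by the genotype coding), the likelihood of
\(J = (J_1, \dots, J_9)\) is

\[
L(J) \;=\; \prod_{l=1}^{L} \sum_{m=1}^{9}
  J_m \; P(D^a_l, D^b_l \mid X_l = m, f_l),
\]

where the emission term integrates the genotype-pair prior over the
genotype likelihoods:

\[
P(D^a_l, D^b_l \mid X_l = m, f_l) = \sum_{g,h \in \{0,1,2\}}
  P(D^a_l \mid g)\, P(D^b_l \mid h)\, P(g, h \mid f_l, m).
\]

The genotype-pair priors \(P(g, h \mid f, m)\) are generated
programmatically from the set partitions that define the nine states: every
IBD block draws one allele independently (frequency \(f\) for the counted
allele) and the genotypes are the induced allele counts
(`genotypePairPrior()`, `statePartitions()`).  Generating the full
9-state-by-9-genotype-pair table from first principles avoids transcription
errors; the classical identity-state table with called genotypes is kept as
a regression test, and with one-hot likelihoods the model reduces exactly to
that called-genotype method.  Triallelic sites are assumed removed upstream,
and the frequency refers to the second-listed allele of the input file —
this package does not fold or re-polarise frequencies.

Because each factor is linear in \(J\) and \(\log\) is concave, the
composite log-likelihood is concave on the simplex: every local maximum is
global.  Multi-start EM is therefore a safeguard of the stopping rule rather
than a search over basins, which is why the validation runs use a single
start while the user-facing default (`nRestarts = 5`) keeps the conservative
behaviour.

If sites are linked the product above is a composite likelihood; the
estimates remain consistent, but no LD correction is attempted.

## Maximisation: accelerated EM on the simplex

The EM update is the posterior mean of the per-site state indicators,

\[
J'_m = \frac{1}{L} \sum_l
  \frac{J_m e_{lm}}{\sum_{m'} J_{m'} e_{lm'}},
\]

which stays on the simplex and never decreases the log-likelihood.  Plain
EM crawls near flat directions, so `estimateJacquard()` wraps it in a
squared-iterative (SQUAREM, scheme S3) acceleration: from two plain steps it
forms \(r = J^{(1)} - J\), \(v = J^{(2)} - J^{(1)} - r\), step length
\(\alpha = -\lVert r \rVert / \lVert v \rVert\) (capped at \(-64\)) and the
extrapolated proposal \(J - 2\alpha r + \alpha^2 v\).  Numerical choices:

* the proposal is projected onto the simplex by flooring at \(10^{-12}\)
  and renormalising;
* a proposal that does not improve on the plain double step is step-halved
  (\(\alpha \to (\alpha - 1)/2\), at most 5 times) and, failing that, the
  cycle falls back to the plain double step — ascent is therefore monotone
  by construction;
* convergence is declared when the absolute log-likelihood change per cycle
  falls below `tol` (default `1e-9`), or after `maxIter` (default 5000)
  cycles, in which case the result is flagged unconverged;
* start points are uniform-Dirichlet draws on the simplex, reproducible
  from `seed`; reruns with the same seed are bit-identical.

After convergence the boundary of the parameter space is examined
automatically: coefficients below `1e-5` are clamped to exactly zero and
the vector renormalised; the clamped solution is kept when its
log-likelihood is within `tol` of the unclamped one.  This replaces a
manual inspection step with a deterministic rule.

### Identifiability

For biallelic markers the nine emission distributions are linearly
dependent: for every frequency, the direction
\((0, -1, 0, 1, 0, 1, 1, -2, 0)\) in \(J\)-space leaves all genotype-pair
probabilities unchanged.  The maximiser is therefore generically a segment,
not a point, unless the simplex boundary pins it (as it does at vertex-type
optima such as unrelated or parent-offspring pairs).  Two consequences
shape the package's contracts and tests:

* relatedness `rab`, the inbreeding coefficients `Fa`/`Fb`, kinship
  `theta`, `ibd23` and `Fdiff` are orthogonal to that direction and hence
  invariant across equally likely solutions — these are the quantities the
  package treats as reliably estimated;
* individual coefficients from two equally converged runs (different
  seeds, or accelerated vs plain EM) may legitimately differ by far more
  than the convergence tolerance.  Optimiser comparisons in the test suite
  therefore compare the maximised log-likelihood and the invariant
  statistics, not raw coefficients.

## Derived statistics

`ibdStats()` evaluates the standard linear combinations (relatedness,
inbreeding, kinship, fraternity, identity, zygosity, `ibd23`, `Fdiff`).
`estimate2dSfs()` estimates the pairwise 3×3 joint genotype-class
distribution by the same EM machinery applied to the nine genotype-pair
likelihood products — no allele frequencies required, uniform start,
deterministic.  `ibsStats()` turns that spectrum into `R0`, `R1` and the
KING-robust kinship, with cells labelled `A..I` row-major so that `E` is
the double-heterozygote cell and `C`, `G` the opposite homozygotes — the
only orientation under which the three ratios reduce to their published
definitions.  These IBS statistics assume non-inbred individuals; ratios
with zero denominators are reported as `NaN` rather than as errors so that
multi-pair tabulation can continue.

A site-level bootstrap (`bootstrapPair()`) resamples sites with
replacement, re-estimates everything per replicate and reports percentile
intervals.  The resampling unit is the site, consistent with the
independence assumption of the likelihood; block bootstraps for linked data
are out of scope.  Defaults: 200 replicates, 95% level.

## The simulator and its scenarios

`geneDrop()` implements the generative model the package is validated
against: site frequencies drawn from Uniform(`maf`, 1 − `maf`) (the
minor-allele-frequency filter applied at sampling time), founder genotypes
as two independent Bernoulli draws (Hardy–Weinberg), and each non-founder
inheriting one uniformly chosen allele per parent per site.  Founder-allele
labels are propagated so the realised IBD state of any pair is known at
every site (`ibdStates()`).  Sequencing is layered on by `simulateGL()`:
per-site read depth Poisson(`depth`), each read sampling one chromosome
uniformly and mis-read with probability `error` (default 0.001), genotype
likelihoods as products of per-read probabilities, flat rows at zero depth.

`expectedJacquard()` is the exact counterpart: it enumerates all
\(2^{2n}\) transmission patterns of a pedigree with \(n\) non-founders and
averages the resulting condensed states.  This is exact, fast for the
validation pedigrees (at most \(2^{14}\) patterns here; the budget guard
suggests Monte-Carlo gene dropping beyond 20 meioses), and validates the
gene dropper in distribution.

Three fixed scenarios (`scenarioPedigree()`) define the study conditions:

1. **outbred first cousins** — two full-sib parents married to founders;
   exact truth \(J_8 = 0.25\), \(J_9 = 0.75\), \(R = 0.125\);
2. **cousin pair with one inbred individual** — individual `b` is the
   child of a father–daughter mating (parents related as parent–child), so
   \(F_b = 0.25\); exact truth
   \(J = (0, 0, 0, 0, 0.0625, 0.1875, 0, 0.375, 0.375)\), \(R = 0.2344\);
3. **both individuals inbred** — `b` as in scenario 2 plus an uncle–niece
   mating (parents related as grandparent–grandchild, kinship 1/8) on the
   other side; exact truth \(R = 0.3828\), \(F_1 = 0.25\), \(F_2 = 0.125\).

These reconstructions were validated against their exact coefficients
before being frozen; alternative matings with the same parental kinship
(e.g. a child-of-child mating for scenario 2) produce different
cross-coefficients and were rejected.

**What the simulator does not emulate.**  No linkage disequilibrium or
recombination maps, no mutation, no allosomes, no reference bias, no
alignment or duplicate artefacts, symmetric single-parameter base error
only, and the estimator receives the *true* simulated frequencies.  Passing
the validation therefore demonstrates correctness of the statistical
machinery under the model's own assumptions; on real data, frequency
misestimation, LD and platform-specific error structure will add error that
these tests cannot see.

## Validation scale

The end-to-end recovery checks use 25 replicates per scenario at 50,000
sites, mean depth 8 and a 0.1 MAF filter — sizes chosen to hold the
Monte-Carlo error of the replicate mean near 0.002, an order of magnitude
below the 0.02 acceptance band.  Optimiser-agreement checks run at 1,000
sites and depth 16 where both EM variants converge fully; property checks
(monotonicity, simplex closure, determinism) use thousands of small random
instances.  The acceptance script (`scripts/acceptance.R`) recomputes the
exact scenario coefficients and the replicate means from scratch at exactly
these sizes.

## Known limitations

* Frequencies are taken as known; jointly estimating them, or folding
  minor/major coding, is out of scope.
* BCF and binary PLINK inputs are not parsed natively; convert with
  `bcftools view` upstream.  Likelihood computation from raw reads (BAM or
  CRAM pileups) is delegated to external callers.
* Individual `J` coefficients are reported as estimated but are only
  identified up to the flat direction described above; trust the invariant
  summaries when the pedigree may involve inbreeding loops.
* The site bootstrap understates uncertainty when sites are strongly
  linked.
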