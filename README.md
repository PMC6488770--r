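# relateGL

Relatedness and inbreeding estimation for pairs of diploid individuals
directly from genotype likelihoods — no genotype calling required.

## What it does, and for whom

Low-coverage sequencing data cannot support reliable genotype calls, which
breaks classical relatedness estimators (PLINK-style method-of-moments,
KING, maximum-likelihood Cotterman estimators) and every tool that infers
inbreeding from called genotypes.  relateGL is for population, conservation
and medical geneticists who have per-site genotype likelihoods
P(D | G = 0, 1, 2) from a caller such as ANGSD, GATK or bcftools, plus
population allele frequencies, and want pairwise relatedness that remains
valid when individuals are inbred.

The central quantity is the vector of nine condensed Jacquard coefficients
**J** = (J1, …, J9): the genome-wide frequencies of the nine condensed
identity-by-descent configurations of the four gene copies of a pair.  For
L unlinked biallelic sites the composite likelihood is

    L(J) = prod_l  sum_m  J_m · P(D_a, D_b | X_l = m, f_l),

with the emission term summing the genotype-pair prior under state m over
all genotype pairs, weighted by the genotype likelihoods.  relateGL
maximises this over the probability simplex with a SQUAREM-accelerated EM
(monotone, multi-start, boundary-examined), and derives

* IBD summaries: relatedness `rab = J1 + J7 + 0.75(J3+J5) + 0.5·J8`,
  inbreeding coefficients `Fa = J1+J2+J3+J4`, `Fb = J1+J2+J5+J6`, kinship
  `theta = J1 + 0.5(J3+J5+J7) + 0.25·J8`, fraternity, identity, zygosity,
  `ibd23`, `Fdiff`;
* IBS summaries from the pairwise 3×3 2D site frequency spectrum estimated
  by EM from the same likelihoods (no frequencies needed): `R0`, `R1` and
  the KING-robust kinship;
* site-bootstrap percentile confidence intervals for all of the above.

A pedigree simulator (gene dropping with founder-allele tracking, Poisson
read depths, symmetric base error) and an exact identity-coefficient oracle
(enumeration of all transmission patterns) generate validation data from
three fixed scenarios of increasing inbreeding complexity.

## Worked example

Simulate scenario 2 (first-cousin-like pair where individual `b` is the
child of a father–daughter mating, so its true inbreeding coefficient is
0.25) at 10,000 sites and mean depth 4, then estimate:

```r
library(relateGL)

sim <- simulateScenario(2, nSites = 10000, depth = 4, error = 0.001,
                        maf = 0.1, seed = 42)
est <- estimatePair(glMatrix(sim$gl, "a"), glMatrix(sim$gl, "b"),
                    alleleFreq(sim$gl), seed = 1)
est
#> JacquardEstimate (9 condensed identity coefficients)
#>     J1     J2     J3     J4     J5     J6     J7     J8     J9
#> 0.0000 0.0024 0.0075 0.0051 0.0653 0.1878 0.0739 0.2057 0.4523
#>   rab = 0.2314  Fa = 0.0150  Fb = 0.2555  theta = 0.1248
#>   loglik = -16279.3654 over 10000 sites; 151 iterations; converged
#>   on boundary: J1

round(sim$expectedJ, 4)
#>     J1     J2     J3     J4     J5     J6     J7     J8     J9
#> 0.0000 0.0000 0.0000 0.0000 0.0625 0.1875 0.0000 0.3750 0.3750
```

At this low depth the individual coefficients are noisy (J7/J8/J9 trade off
along a known flat direction of the model), but the invariant summaries are
already accurate: estimated relatedness 0.231 against a true 0.234, and
estimated `Fb` 0.256 against a true 0.25.  The allele-frequency-free IBS
statistics come from the pairwise spectrum:

```r
sfs <- estimate2dSfs(glMatrix(sim$gl, "a"), glMatrix(sim$gl, "b"))
round(ibsStats(sfs), 4)
#>      R0      R1    King
#>  0.5329  0.3053 -0.0139
```

(KING assumes non-inbred individuals, which is exactly what breaks here —
the reason to estimate the full Jacquard vector.)

### Command line

```sh
Rscript $(Rscript -e 'cat(system.file("cli", "relategl.R", package = "relateGL"))') \
    simulate --scenario 2 --sites 10000 --depth 4 --seed 42 --out-prefix sim
# ... estimate --gl sim.beagle.gz --freq sim.freq --out results.tsv --seed 1
# ... sfs      --gl sim.beagle.gz --out sfs.tsv
```

`estimate` accepts beagle GL tables (gzip ok) or VCF with `GL`/`PL` tags,
a frequency file or `--af-from-info`, an optional pair list, bootstrap
options (`--boot`, `--level`) and `--threads` (changes wall time only,
never results).  Output is a TSV with columns `ida idb J1..J9 rab Fa Fb
theta F12 F21 fraternity identity zygosity ibd23 Fdiff R0 R1 King loglik
nSites nIter converged seed`.

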