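# paleocanid

Desk-scale tools for ancient-canid paleogenomics: damage-aware genotype
calling for ancient DNA, f-statistics with admixture-graph fitting, a
coalescent derived-allele-sharing estimator of population divergence time
calibrated by sample age, read-depth copy-number estimation (the amylase
`AMY2B` locus being the motivating case), and divergence-based
neighbour-joining trees with dog/wolf haplotype classification — all
exercised end-to-end on synthetic data generated by the package's own
structured-coalescent simulator.

## The problem and who this is for

Ancient dog genomes carry post-mortem deamination damage (C→T near 5′
read ends, G→A near 3′ ends on the complementary strand) that mimics real
variation, inflates heterozygous calls, and stretches inferred branch
lengths. The package is aimed at population geneticists who want to

1. model that damage explicitly and call genotypes through it,
2. measure relatedness and admixture with f-statistics, and
3. date the split between an ancient lineage and its modern sister clade
   with an estimator that is *robust* to residual damage, because it uses
   only sites already known variable in high-coverage modern genomes and
   only one chromosome per population.

## The models at the core

**Damage decay.** The misincorporation proportion at 1-based position *x*
from a read end is fit as a Weibull decay

> d(x) = a · exp(−(x^c) · b),  a ∈ [0,1], b > 0, c > 0

(c = 1 is plain exponential; a free shape c usually fits slightly
better). The genotype likelihood of each read composes damage before
sequencing error: P(o | g) = Σ_b P_err(o | b; ε) · P_dam(b | g; x,
orientation), with ε from the Phred quality capped at 40, reads with
mapping quality < 15 and bases < 15 excluded. Calls require ≥ 7×
effective depth (else missing), and a best heterozygote with GQ < 30 is
demoted to the best homozygote.

**f-statistics.** Patterson estimators f2 = E[(a−b)²],
f3(C; A, B) = E[(c−a)(c−b)], f4(A,B; C,D) = E[(a−b)(c−d)], the
D-statistic, and the f4-ratio estimator of an admixture proportion α;
standard errors by weighted delete-one-block jackknife. Expected
f-statistics on a user-specified admixture graph are computed by
admixture-weighted path summation, and graphs are fit by bounded weighted
least squares with |Z| ≥ 3 residuals reported as outliers.

**Divergence dating.** With single chromosomes from the ancient sample
(ANC), Europe (EUR), India (IND) and Asia, the ratio

> R = n(derived exclusive to ANC+EUR) / n(derived exclusive to EUR+IND)

has a closed coalescent expectation under a structured model with
parameters (θ₁, θ₂, P₀, P₂, P₃, α) in mutation-scaled units — population
sizes θ = 4Nμ, divergence times τ in expected mutations per site. The
expectation is computed exactly by piecewise matrix exponentials on the
partition Markov chain of the four lineages, is strictly decreasing in
the ancient–European divergence τ₁, and is inverted by bisection to date
τ₁ from an observed R. Calendar time follows from years = g·τ/μ, and a
dated sample bounds the mutation rate from above via μ ≤ g·τ₁/age.

**Copy number.** Per-position read depth is GC-corrected by a loess fit
in copy-number-stable control regions, averaged in 3 kb windows, and
converted to copy number as CN = 2 × depth / control mean; locus calls
take the median window CN rounded to an integer.

## Worked example: dating an ancient lineage

```r
library(paleocanid)

demo  <- study_demography()                 # 4 pops + outgroup, tau1 = 0.0015
panel <- simulate_genotypes(demo, 1e5, seed = 7)
panel
#> Genotype panel: 100000 sites x 8 samples ( 5 populations, 200 blocks )
#>   polarized: TRUE  missing: 0

keep <- modern_variable_sites(panel, c("EUR", "IND", "ASIA"))
hp   <- haploidize(panel, c(ANC = "anc1", EUR = "eur1",
                            IND = "ind1", ASIA = "asia1"), seed = 7)
counts <- count_sharing_patterns(hp, sites_keep = keep)
counts
#> Exclusive derived-allele sharing (strict):
#>   ancient+European: 115   European+Indian: 95   ( 4535 sites, 200 blocks )

R <- sharing_ratio(counts)
R
#> Sharing ratio R = 1.2105 (95% CI 0.8795-1.5416, 200 blocks)

cp  <- coal_params(theta1 = 0.01, theta2 = 0.01, P0 = 5e-4,
                   P2 = 2e-3, P3 = 3e-3, alpha = 0.2)
solve_tau1(R, cp)
#> tau1 = 0.00141861 mutations/site (CI 0.000947718-0.00197982) from R = 1.2105
```

The ancient lineage shares more derived alleles with Europe than India
does (R > 1), and inverting the coalescent expectation dates the
ancient–European split at τ̂₁ = 0.00142 mutations/site — the simulated
truth (0.0015) sits inside the jackknife confidence interval. Calendar
calibration is then one line: `calibrate_time(tau1, mu = 4e-9, g = 3)`
converts a mutation-scaled divergence into years given a per-generation
mutation rate and a generation time.

A full synthetic study — damage refit, damage-aware calling versus a
damage-naive caller, f4-ratio admixture, dating, copy number and F1
locus classification — runs with `run_synthetic_study(seed = 1)`.

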