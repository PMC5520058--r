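---
title: "Models and methods behind paleocanid"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind paleocanid}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paleocanid)
```

This vignette explains the statistical models the package implements,
the assumptions behind them, the tunable parameters and their defaults,
and the design decisions taken where more than one reasonable choice
existed. The package's test suite computes every empirical claim made
here; nothing below rests on results the code does not itself produce.

## 1. Units: mutation-scaled time

All demographic quantities are mutation-scaled: a divergence time τ is
the expected number of mutations per site accumulated since the split,
and a population size θ = 4Nμ, so that two lineages in a population of
size θ coalesce at rate 2/θ per unit of mutation-scaled time. The merit
of this convention is that nothing in the simulation, the f-statistics
or the dating expectation depends on the per-generation mutation rate μ;
calendar time enters only at the very end through

* `calibrate_time(tau, mu, g)` = g·τ/μ years, and
* `mu_upper(tau1, age, g)` = g·τ₁/age — a dated ancient sample must be
  younger than the calendar time since its divergence from the modern
  sister lineage, which bounds μ from above.

The two functions are exact inverses: calibrating τ₁ with its own
age-derived bound returns the sample age identically, a property the
test suite asserts.

## 2. The coalescent simulator

`simulate_genotypes()` draws one independent single-locus genealogy per
site under a piecewise-constant structured coalescent: populations merge
backwards in time at split times, admixture pulses move a lineage from
one population to another with the pulse probability, and ancient
samples enter the genealogy at their (mutation-scaled) age. Mutations
are Poisson on branches with rate one per unit branch length, and a
chromosome is *derived* when the mutation count on its root path is odd
— at the θ values in play, multiple hits are vanishingly rare and this
is the infinite-sites limit. The core loop is C++ (via Rcpp) because the
parameter-recovery experiments simulate on the order of 10⁷ genealogies.

Ascertainment ("only sites variable in panel X") is implemented by
rejection: a site is resimulated until it is polymorphic among the
designated panel's chromosomes. This matches discovery-panel
conditioning and makes the flag explicit rather than implicit in a
filtered output.

What the generator deliberately does *not* emulate: recombination within
loci (sites are unlinked; jackknife blocks are contiguous chunks of 500
sites by default purely to exercise the block machinery), selection,
sequencing-machine error structure beyond per-base Phred scores, and
reference/mapping bias. Passing tests therefore demonstrate correctness
of the estimators under their own model assumptions, not robustness to
every artefact of real ancient-DNA data.

The default synthetic study (`study_demography()`) uses divergence
ratios τ₁ : P₂ : P₃ = 0.75 : 1 : 1.5 with an Asian admixture fraction
α = 0.2 into the ancient lineage and equal sizes θ = 0.01 throughout.
The expected sharing ratio is invariant under joint rescaling of all
times and sizes, and these values are a ratio-preserving rescaling of
modern-dog point estimates chosen so that panels of 10⁵–2×10⁵ unlinked
sites carry informative exclusive-sharing counts (a few hundred per
panel); at raw genome-scale magnitudes (θ ≈ 10⁻⁴) those counts would
need millions of sites, which is what the real studies use. The ancient
sample age defaults to 0.001 (< τ₁), and the Asian-derived fraction of
the ancient lineage travels through a ghost population that only rejoins
at the (Europe,India)/Asia split — see §5.

## 3. Damage model and damage-aware calling

### Decay form

Terminal deamination is tabulated strand-resolved: reference C read as T
by position from the 5′ end, reference G read as A from the 3′ end, with
reverse-orientation reads complement-relabelled first (the same chemical
event presents as G→A near a reverse read's 5′ end in reference-forward
coordinates). The proportions are fit by weighted bounded
Levenberg–Marquardt least squares (via minpack.lm) to

d(x) = a·exp(−(x^c)·b),

weights proportional to opportunities, over the first 25 positions from
each end (damage is negligible deeper into reads; configurable). Bounds
are a ∈ [0,1], b ∈ (0,50], c ∈ (0,5]; starts are a ← proportion at
position 1, b ← the log-linear slope over the first ten positions,
c ← 1. Because a, b and c trade off in small tables, stable amplitude
recovery wants on the order of 10³–10⁴ opportunities per position; the
free-shape fit never has larger weighted RSS than the exponential
(c = 1) special case, which the suite asserts. A sequencing-error floor
estimated from interior positions (≥ 25) is subtracted before fitting by
default, since the tabulated proportion at a position is damage plus a
roughly position-independent error term. Each read end is fit
independently; nothing in the data ties the two decays together.

### Likelihoods and calling rules

Per retained read (mapping quality ≥ 15, base quality ≥ 15, quality
capped at 40 before conversion to ε), the observation probability given
a true allele composes **damage first, then sequencing error**:

P(o | g) = Σ_b P_err(o | b; ε) · P_dam(b | g; position, orientation),

with P_err(o | b) = 1−ε if o = b, else ε/3. A diploid genotype averages
its two alleles and the site log-likelihood sums over reads; all ten
unordered genotypes get likelihoods and ties at the maximum break by
fixed genotype order for determinism. The composition order is a
modelling choice (the template is damaged before it is sequenced); the
brute-force per-read oracle in the tests implements the same order
independently and agrees to 10⁻¹⁰.

Calling uses a flat genotype prior. Effective depth < 7 reports the site
missing. If the maximum-likelihood genotype is heterozygous with
Phred-scaled GQ (10/ln 10 times the log-likelihood gap to the runner-up)
below 30, the best homozygote is emitted instead, annotated
`het-demoted`, with GQ recomputed against the best remaining genotype —
recomputation rather than inheritance is a deliberate choice, flagged in
the documentation because the alternative is defensible. The threshold
is inclusive: GQ exactly 30 keeps the heterozygote. With amplitude a = 0
the whole machinery collapses exactly to a standard flat-prior caller,
which the suite checks to 10⁻¹².

The mechanism the damage-aware likelihood suppresses is concrete: a C/C
site with a few terminal T reads looks heterozygous to a damage-naive
caller, while the damage term explains those reads at their observed
positions. On paired simulations the damage-aware caller's false-het
count at homozygous truth is strictly below the naive caller's.

## 4. f-statistics, jackknife, graphs

Per-site estimators are the standard frequency products (§README). Two
details:

* **Finite-sample correction.** f2 and f3 subtract the heterozygosity
  terms p̂(1−p̂)/(n−1) (both populations for f2, the target for f3) when
  sample sizes are available and the flag is on. The flag exists because
  pseudo-haploid ancient samples violate the correction's assumptions;
  both modes are first-class.
* **Weighted block jackknife.** Delete-one-block with weights
  proportional to per-block site counts, in the Busing form, applied to
  the ratio itself for ratio statistics (D, f4-ratio, the sharing
  ratio). Blocks default to the panel's `block_id`; `genetic_blocks()`
  builds 5 cM windows from a two-column (pos, cM) map by linear
  interpolation.

Expected f-statistics on an admixture graph use edge-usage
probabilities: u_e(X) is the probability that edge e lies on the lineage
route from leaf X to the root, computed by mass propagation through the
DAG, and E f4(A,B; C,D) = Σ_e ℓ_e (u_e(A)−u_e(B))(u_e(C)−u_e(D)). A
brute-force enumerator over independent lineage routings serves as the
oracle in tests. Graph fitting exploits that expectations are *linear*
in edge lengths at fixed admixture proportions: lengths are profiled out
by weighted linear least squares (refit under the non-negativity bound
when needed) and only the proportions are optimized numerically, from
several starts. Identifiability is diagnosed by the rank of the weighted
design matrix; the null space is returned when deficient. Note the
classic degeneracy: the two root-incident edges of a degree-2 root are
never separately identifiable from f-statistics, so fixtures and users
should root graphs at nodes of degree ≥ 3. Statistics with
|standardized residual| ≥ 3 are reported as outliers — the conventional
boundary for calling a fit poor. Automated topology search is out of
scope; users supply the graph.

## 5. The sharing-ratio dating model

Four haploid lineages — ancient (a), European (e), Indian (i), Asian
(s) — evolve backwards through three epochs: [τ₁, P₂) where a and e
share the European-ancestral population of size θ₁ (with probability
1−α; the Asian-derived fraction α of the ancient lineage is inert until
P₃), [P₂, P₃) where survivors and i interact at pairwise rate 2/θ₂, and
[P₃, ∞) where everything coalesces in a population of size θ_anc. The
expected count of sites whose derived allele is exclusive to a sample
pair equals the expected branch length subtending exactly that pair, so

E[R] = E[L({a,e})] / E[L({e,i})],

computed exactly as the occupancy of pair-subtending states of the
continuous-time Markov chain on the 15 set partitions of the four
lineages: within an epoch the generator is constant, occupancies are
matrix exponentials (an augmented-matrix form gives the integral), and
the final epoch uses the fundamental matrix of the absorbing chain. This
is closed-form up to `expm`, with no quadrature error to tune.

Decisions the model text leaves open, and what the package does:

* **θ_anc.** The exclusive-pair branch keeps accruing length above P₃
  until its first coalescence, so the expectation depends on the
  ancestral size above P₃ even though the conditioning parameter list
  stops at θ₂. Default θ_anc = θ₂, exposed as a field; the Monte-Carlo
  oracle uses the same convention.
* **Admixture timing.** The Asian-derived fraction of the ancient
  lineage joins only at/above P₃. Both counted patterns depend only on
  branches above τ₁, which makes results insensitive to exactly when
  below P₃ the pulse happens; the simulator realizes the same convention
  with a ghost population so simulation and expectation agree by
  construction.
* **Sample age.** The ancient tip is truncated at its age in the
  simulator, but the expectation needs no age term: both counted
  patterns require the a+e (or e+i) pair to have already coalesced,
  which can only happen above τ₁ ≥ age.
* **Strictness.** Whether the denominator (and numerator) condition on
  the Asian chromosome being ancestral is a flag, default strict; the
  Monte-Carlo oracle validates both settings.
* **Ascertainment.** Counting restricts to sites variable among the
  modern populations. Both counted patterns have a derived European
  chromosome and an ancestral Asian one, so they pass modern
  ascertainment automatically and the restriction cancels from the
  expectation — it is what buys robustness to damage-driven errors in
  the ancient genome, a property the suite tests by corrupting an
  ancient sample at non-ascertained sites and observing an unchanged
  ratio.

`solve_tau1()` inverts the strictly decreasing map τ₁ ↦ E[R] by
bisection on [P₀, P₂] (tolerance 10⁻¹² in τ₁); the confidence interval
is the range of solutions over (posterior parameter draw, ratio-CI
endpoint) pairs, with endpoint targets outside the attainable ratio
range clamped to the boundary — the point solve instead raises an error
naming the attainable interval, because silently clamping a point
estimate would hide model misfit. A synthetic-posterior generator
(independent truncated normals) stands in for real sampler draws in
tests and is labelled as synthetic.

Because the analytic expectation could be wrong in ways its own tests
would not catch, the binding correctness check is an independent
stochastic simulator of the same four-lineage process (C++, exponential
clocks, no shared code with the Markov-chain path): the suite compares
the two across a 27-point grid in (τ₁, α, θ₁) at three Monte-Carlo
standard errors, and checks the exchangeability identity E[R] = 1 at
α = 0, τ₁ = P₂ exactly.

## 6. Copy number from read depth

Depth is averaged in 3 kb windows (terminal remainder kept), loess of
depth on GC (span 0.3, widened automatically when control windows are
scarce so the local quadratic keeps support) is fit in control regions
only, and corrected depth is raw × control mean / loess(GC), rescaled so
the control mean is preserved exactly. GC outside the fitted support
uses nearest-endpoint extrapolation and is flagged. Copy number is
2 × corrected window depth / control mean; a locus call is the median
over overlapping windows rounded half away from zero. The upstream
read-splitting/multi-mapping pipeline that produces per-position depth
tracks for repetitive loci is out of scope — the module consumes depth,
which keeps it format-agnostic. Copy-number estimates are scale
invariant in depth units and unbiased to < 0.05 copies at 9× in the
suite's Poisson simulations.

## 7. Trees and locus classification

Pairwise divergence is the probability two randomly drawn alleles
differ, d(x,y) = mean of p_x(1−p_y) + p_y(1−p_x) with p = dosage/ploidy,
dropped pairwise on missingness. Neighbour joining is delegated to
`ape::nj` with labels sorted first so tie-breaking is deterministic.
Window bootstrap resamples 5 cM windows (or the panel's blocks) with
replacement and reports the fraction of replicate trees containing each
original bipartition.

Locus classification against dog and wolf reference panels uses a
centroid rule: per window, after filtering to minor allele frequencies
in [0.05, 0.49] across the combined panels (a flag restores all sites),
the query's mean absolute dosage distance to the dog and wolf centroids
is compared; a margin of 0.25 dosage units separates `dog-like` /
`wolf-like` from `heterozygous-like`, and windows with fewer than 20
usable sites stay unclassified. The underlying decision statistic in the
literature is described only as average reference-allele counts per
window; the centroid rule is this package's codified version, validated
on simulation (an F1 dog×wolf query classifies heterozygous-like in
≥ 90% of windows) rather than against any published per-locus table.

## 8. Problem sizes and determinism

The test suite and the acceptance script run at deliberately desk-scale
sizes chosen as the smallest that leave the assertions statistically
comfortable: 10⁵ sites for frequency-based checks, 2×10⁵ sites × 100
replicates for the τ₁ recovery experiment, 2×10⁵ genealogies per grid
point for the dating oracle, 10⁴ sites for the paired caller comparison,
and 10⁴ opportunities per position × 100 replicates for damage-fit
recovery. Every stochastic operation takes an explicit seed, and
identical seeds give bit-identical outputs, including file outputs
(VCF bodies, JSON reports).

## 9. Known limitations

* The damage model covers double-stranded library chemistry
  (5′ C>T / 3′ G>A); single-stranded protocols and UDG-treated
  libraries have different signatures and are not modelled.
* The caller is single-sample, SNV-only, flat-prior; no indels, no
  realignment, no recalibration.
* Unlinked-sites simulation means jackknife blocks exercise machinery
  rather than model true linkage; real-data block SEs depend on
  recombination structure the generator does not produce.
* The dating expectation conditions on externally supplied demographic
  parameters; it does not infer θ/P jointly with τ₁, and posterior
  draws for the CI must come from an external sampler (or the labelled
  synthetic generator).
* The sharing-ratio model assumes a clean ((ancient, Europe), India)
  Asia topology with a single admixture pulse; pervasive low-level gene
  flow between the modern populations would bias τ̂₁ in ways the model
  cannot see.
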