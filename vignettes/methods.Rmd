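---
title: "Methods: models, parameters and design choices in mamut"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in mamut}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(mamut)
```

This vignette is the package's own account of the science it implements: the
models and their assumptions, the tunable parameters with their defaults and
why, what the synthetic-data generator emulates (and does not), and the
numerical and design choices made where the design was genuinely open. It
states no empirical result that the test suite or `scripts/acceptance.R` do
not themselves compute.

## 1. The mutation-accumulation model

An MA experiment founds many lines from a single progenitor colony and
passages each through a single random colony every day. The per-passage
bottleneck of one cell makes the within-line effective population size so
small that selection is impotent: nearly all mutations — beneficial,
neutral, deleterious — fix by drift. Under this regime the observed mutation
count per line is, to excellent approximation, a Poisson draw with mean
$u \cdot G \cdot n$ for per-site rates ($u \cdot G$ for per-genome SV
rates), which is exactly what the estimators invert:

$$ u_{\mathrm{SNM,SIM}} = \frac{m}{G\,n}, \qquad u_{\mathrm{SV}} = \frac{m}{G}. $$

**Assumptions.** (i) No within-line recurrence at a site: at realistic rates
(u ≈ 1e-10 to 1e-7 per site) and desk scales (G ≈ 1500, n ≈ 4.6e6),
expected double hits are ≪ 1, and the MA design fixes one allele per site
anyway; the simulator therefore places mutations without replacement within
a line. (ii) All covered ancestral sites are equally mutable given their
trinucleotide context. (iii) Generation counts G are known inputs; the
package takes per-passage generation values as data (how colony CFU counts
convert to generations is a wet-lab calibration outside this artifact) and
implements only the two-segment weighting

$$ G = \frac{(G_0+G_{30})a + (G_{30}+G_N)b}{N}, \quad a = 15,\; b = N/2-15, $$

which linearly interpolates the per-passage generation number between the
day-0/day-30 average (first 30 days) and the day-30/last-day average (the
remainder); it requires N ≥ 30 and reduces to the constant when
$G_0 = G_{30} = G_N$.

**Outlier exclusion.** Within one progenitor and one mutation class, a line
is excluded when $|u - U|/S > 2.5$ with U, S the mean and *sample* (n−1)
standard deviation over all lines of that progenitor. The n−1 convention is
a choice (the source procedure does not specify the denominator); it is the
more conservative of the two (larger S, fewer exclusions) and is
configurable. Exclusion is single-pass — U and S are not recomputed after
removals — and applied independently per class.

**Group comparison.** Welch's unequal-variance two-tailed t-test is the
default (the toolchain convention for "unpaired t-tests"; equal-variance
Student's is available by flag). Fold changes are ratios of group means.

## 2. Variant filtering

The filter stage reproduces standard MA post-calling logic, as pure
partitions (no call is ever modified):

* depth ≥ 4 and phred ≥ 10 kept — the discard rule is strict ("< 4",
  "< 10"), so the boundary values 4 and 10 are kept;
* ancestral variants (progenitor vs reference differences) subtracted by
  exact (chrom, pos, ref, alt) key;
* consensus removal: an SNM key in **more than two** lines (SIM: more than
  four) of one progenitor is removed everywhere. "More than" is read as
  strict inequality — removal at ≥ 3 (SNM) and ≥ 5 (SIM) lines; both limits
  are configurable should the inclusive reading (≥ 2 / ≥ 4) be wanted;
* indels of 1–4 bp are SIMs; a 5-bp indel is an SV (boundary tested);
* SV dedup across callers in precedence order Lumpy → CNVnator →
  BreakDancer: a later-caller SV is redundant iff a retained earlier-caller
  SV of the same type has both interval ends within 500 bp. Requiring the
  same `sv_type` across callers is an assumption (configurable in
  principle); so is the precedence list;
* SV ancestral/parallel removal: match to an ancestral SV, or a match-class
  spanning ≥ 3 lines. Match-classes are built by **single linkage** over the
  pairwise both-ends-within-window relation; transitivity is not defined by
  the source procedure, and single linkage is the most conservative grouping
  for removal (it removes more, never less, than any refinement).

Composing the stages is idempotent, which the suite checks by re-filtering
filtered output.

## 3. Serial-transfer demography

For dilution factor D and carrying capacity K, one growth cycle starts at
the bottleneck $N_0 = KD$ and doubles back to K. The census snapshots are
the integer doublings $N_0 2^i$ strictly below K, followed by K itself, and
Ne is their harmonic mean. This snapshot convention was chosen because it
reproduces the printed five-term harmonic-mean computation for the daily
1/10 regime term-for-term (1e9, 2e9, 4e9, 8e9, 1e10 → Ne ≈ 2.53e9) and the
1/1e4 regime's Ne ≈ 7.5e6 exactly; it is the single supported convention.
Known limitation: under this same convention the 1/1e7 regime gives
Ne ≈ 1.3e4, not the 1.3e3 sometimes quoted for such schemes — the
discrepancy looks like an exponent slip in the source and is deliberately
not used as a test target. Generations per day are $\log_2(1/D)/T$; the
value 0.25 sometimes quoted for a 100-day transfer cycle is not derivable
from this formula (it would be 0.033) and is likewise excluded.

## 4. Contextual spectra

SNMs are classified by the six pyrimidine-centred substitutions (C>A, C>G,
C>T, T>A, T>C, T>G) and the 5′/3′ flanking bases: 6 × 16 = 96 classes.
When the reference base is a purine, mutation and flanks are
reverse-complemented before labelling (the flanks swap roles), so the class
system is strand-symmetric: reverse-complementing the genome and remapping
the calls leaves the spectrum bit-identical (a property test). Calls at
sequence ends or with any non-ACGT base in the trinucleotide are skipped and
counted; ref-mismatch calls are skipped and recorded as per-call errors.
Label order follows the conventional six blocks with flanks sorted
alphabetically, 5′-major. Counts are canonical; frequencies are derived.
Spectra are *not* normalised by genomic trinucleotide abundance (raw class
proportions are reported), matching the source convention.

## 5. Mutation patterns (NMF)

The 96 × samples count matrix is factorised as $V \approx WH$ with
non-negative W (patterns; columns sum to 1) and H (exposures), by
multiplicative updates minimising the generalised Kullback–Leibler
divergence — the de-facto standard for mutational signatures ("brunet"
behaviour). Frobenius updates exist in the literature but KL is the
shipped objective. Convergence: at most 1e4 iterations or relative
objective change < 1e-8, whichever first; best of `restarts` random
initialisations; every initialisation is seeded deterministically from the
user seed, so results are bit-for-bit reproducible.

**Rank selection.** For each candidate rank, samples are clustered by their
dominant (argmax) exposure in each restart; the consensus matrix of
co-clustering frequencies is converted to a distance, clustered by
average-linkage hierarchical clustering, and scored by the cophenetic
correlation between consensus distances and tree distances. The chosen rank
is the smallest k whose coefficient exceeds the coefficient at k+1 — "starts
decreasing", scanning upward, with ties treated as not decreasing; if no
decrease occurs the largest candidate is returned with a warning flag. The
exact consensus construction inside reference implementations is not
published; this is the standard procedure and is documented as such.
Degenerate input (all samples proportional) has no clustering structure and
returns the warning flag immediately rather than a spurious rank.

**Reference-signature correlation** uses Pearson r on the shared 96-label
order (scale-invariant, so counts vs frequencies is immaterial), with the
conventional display threshold r ≥ 0.7 returned as a mask; zero-variance
vectors yield r = NA.

## 6. Fluctuation tests

Mutant counts across parallel cultures follow the Luria–Delbrück
distribution: mutational events per culture $M \sim \mathrm{Poisson}(m)$,
each founding a clone whose size has the Lea–Coulson tail
$P(S \ge s) = 1/s$ (a mutation arising uniformly in time during exponential
growth). The pmf is computed by the Ma–Sandri–Sarkar recursion
($p_0 = e^{-m}$, $p_k = \frac{m}{k}\sum_{i<k} p_i/(k-i+1)$), implemented in
C++ (it is O(k²)), with a plain-R recursion kept in the test helpers as the
independent oracle. Counts above `k_max` (default 1e4) are right-censored
into the tail mass $1 - \sum p$ — standard practice that keeps the
recursion finite without discarding assays with jackpot cultures.

The MLE of m maximises the censored log-likelihood by Newton–Raphson on the
analytic score (derivative recursions), safeguarded by bisection within a
maintained bracket; the suite checks agreement with a dense grid argmax to
1e-4 relative. All-zero counts are the degenerate boundary: the likelihood
is maximised at m = 0 (the P0 closed form $m = -\ln f_0$ with $f_0 = 1$),
returned with a warning. `mu_hat = m_hat / Nt` is the rate per cell
division; under binary fission, divisions ≈ final cells, so this is also
the per-generation rate per cell. Plating efficiency and partial-plating
corrections are out of scope (whole cultures on selection); a 95% profile
likelihood interval (Δ log-lik = 1.92) is optional. Pre-existing mutations
in the small inoculum are ignored by the standard model, as usual.

## 7. Genomic divergence

Divergence at a timepoint is the plain sum of derived allele frequencies of
detected SNMs; the rate of genomic evolution is the zero-intercept
least-squares slope $\hat\beta = \sum x_i y_i / \sum x_i^2$ with standard
error on n − 1 residual degrees of freedom (no intercept is estimated — the
model class forces a zero origin: zero generations, zero divergence). The
closed form is computed directly; `lm(y ~ x + 0)` serves as the test
oracle. How "guaranteed generations" are counted (generations/day × elapsed
days) is upstream; the regressor is taken as given.

## 8. The synthetic-data generator: what it emulates, and what not

The generator produces every input the pipeline consumes, with the
statistical structure the analysis assumes:

* `gen_genome`: i.i.d. bases at a stated GC fraction. Defaults used in the
  recovery tests: 4.6e6 callable sites (the covered *E. coli* genome scale)
  and GC ≈ 0.508 (*E. coli* K-12's).
* `simulate_ma`: Poisson mutation counts at the stated truth rates —
  defaults 25 lines and G = 1500, the experimental scale — with SNMs placed
  at sites drawn by 96-class context weight, SIM lengths uniform on 1–4 bp,
  SVs per genome. Clean calls get depth ~ Poisson(150) (the ~149× coverage
  typical of these data) and phred 60, so filter behaviour on clean data is
  deterministic. Artifact injection (shared loci, low-depth calls, inflated
  lines with a default 10× factor) exists solely to exercise the filter and
  outlier rules.
* `simulate_fluctuation`: Lea–Coulson clone sizes via
  $\lceil 1/U \rceil - 1$, U uniform on (0,1], zero-size draws discarded,
  capped at Nt. The cap and the discrete approximation distort only the
  extreme tail; the acceptance surface is MLE recovery, not the sampler's
  microstructure.
* `simulate_divergence`: a line through the origin plus truncated Gaussian
  noise.

**What it does not emulate** — hence what a green test does *not*
establish: read-level error, alignment and calling artifacts (depth/quality
are drawn, not derived from reads); selection, clonal interference or
hypermutator dynamics *during* long-term evolution; context-dependent
coverage; real genomic repeat structure (SV calls are placed uniformly).
Recovery tests therefore validate the estimators and filters against their
own model assumptions, not the upstream calling pipeline.

Every generator takes an explicit integer seed and restores the global
random state afterwards; there is no hidden global randomness.

## 9. Numerical choices and degenerate inputs

* Boundary conventions: depth 4 and phred 10 kept; consensus strictly
  "more than"; Z-cutoff strictly "> 2.5"; cophenetic ties "not decreasing".
* S = 0 in Z-scoring (all rates equal) defines all Z = 0, no exclusions.
* Zero-variance inputs: t-test of identical constant groups returns
  t = 0, p = 1; Pearson r of a flat vector is NA.
* `ld_mle` brackets the score root in [1e-8, ≤ 1e6] before Newton steps;
  any step leaving the bracket falls back to bisection.
* NMF guards divisions with machine epsilon; W columns renormalised to sum
  1 with the compensating scale moved into H (the factorization itself is
  unchanged).
* TSV floats are written at 15 significant digits so write→read round-trips
  are lossless to 1e-12.

## 10. Known limitations

* The minimal-VCF dialect covers the 8 mandatory columns plus a line-id
  column and the INFO keys DP/SVTYPE/END/SOURCE/LINE; it is not a full VCF
  parser (multi-sample genotype columns, phasing, symbolic alleles beyond
  `<SV>` are out of scope by design).
* Ne formulas cover the clean serial-dilution cycle only — no selection, no
  fluctuating K, no multi-cycle harmonic means across a 1000-day design.
* The fluctuation model omits phenotypic lag and fitness differences of
  mutants; both bias real assays but are standard omissions.
* Rank selection inherits the known instabilities of consensus NMF at small
  sample counts; the warning flag should be heeded.
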