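---
title: "Scoring pseudospectra against reference NMR spectra: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring pseudospectra against reference NMR spectra: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metabomatchr)
```

## The problem and the model

An untargeted NMR mGWAS regresses every binned ¹H-NMR metabolome feature on
a genetic variant. When the variant shifts the concentration of one
metabolite, the features that associate are precisely those coinciding with
the metabolite's NMR peaks: the per-feature association statistics
(β, s, p), viewed as a function of chemical shift, form a *pseudospectrum*
that mirrors the metabolite's spectrum. `metabomatchr` turns this into an
identification procedure: each candidate metabolite in a reference database
is scored by how strongly the pseudospectrum loads on its *match set*, and
candidates are ranked.

The match set F<sub>δ</sub>(m) contains, in peak mode, all features within
δ ppm of any reference peak of metabolite m; in multiplet mode, all
features inside any multiplet range padded by δ. Distances exactly equal to
δ are included (closed intervals): reference peaks and features typically
live on round ppm grids, and an open convention would make membership
flicker with floating-point representation. Match sets may legitimately be
empty — a spectrum that carries no description for the requested mode is
retained, flagged, and ranked last rather than dropped, so the output
always has one row per candidate.

Two match statistics are available, both reported as −log10 of a tail
probability:

* **χ²-scoring**: T = Σ (β/s)² over the match set, referred to χ² with
  |F| degrees of freedom. Squaring amplifies strong associations and
  ignores effect directions.
* **Z-scoring**: Z = Σ β/s, referred to N(0, |F|). Signals of opposite
  direction cancel, so Z-scoring is preferable when direction coherence is
  informative (high-powered studies); it is harsher on metabolites whose
  match sets straddle opposite-direction associations.

The degrees of freedom equal the matched-feature count in every mode and
variant, including the decorrelated forms. Under either statistic, scores
rank candidates within a pseudospectrum only; they are not comparable
between pseudospectra and carry no significance statement, because features
in real data are not independent.

### Tail conventions

The Z tail is two-sided on |Z| by default. Two considerations fix this
choice: a global flip of allele coding negates every β and should not change
any score, and a singleton match set should give the same score under both
statistics (χ²₁ is the square of a standard normal, so the two-sided normal
tail matches the χ² tail exactly). A one-sided option
(`z_tail = "one_sided"`) remains for users who want direction-specific
scores. All tail probabilities are computed via `log.p = TRUE` survival
functions and never via p-then-log: strong mGWAS associations reach
p ~ 10⁻²⁵⁰, far past double-precision underflow, and scores up to several
hundred must stay exact.

## Decorrelation

Neighboring features are correlated whenever both sit on the same underlying
peaks, and this inflates scores of candidates matching a correlated clump.
Given a user-supplied feature correlation matrix Ĉ, the decorrelated χ²
statistic is the quadratic form t′C⁻¹t with

C = (1 − λ)·Ĉ∘J<sub>δ</sub> + λ·I,

restricted to feature *neighborhoods*: J<sub>δ,fg</sub> = 1 when f and g are
connected by a chain of match-set features each at most 2δ apart. C is
therefore block diagonal over the neighborhood partition and is inverted
block by block. For Z-scoring the sum is unchanged and the null variance
becomes |ΣC<sub>fg</sub>|. The shrinkage parameter λ ∈ (0, 1] regularizes:
λ = 1 disables decorrelation exactly (both decorrelated scores reduce
bit-for-bit to their plain counterparts, a property the tests pin), and
λ = 0 is rejected at construction because unshrunk empirical blocks can be
singular or near-singular and give candidates artificially high scores.
λ = 0.5 is the recommended working value when decorrelation is on. The
package accepts any valid correlation matrix and does not prescribe how it
is estimated; the simulation module uses the sample correlation of the
simulated metabolome columns.

## Variants

* **2-compound** scores every unordered pair (self-pairs included) on the
  union of the two match sets, with blocks recomputed on the union since
  merging can connect neighborhoods. For n metabolites this is
  n(n+1)/2 candidates — 16,290 for a 180-spectrum database — which is
  enumerated exhaustively; no pruning is needed at these sizes.
* **±** splits the pseudospectrum by effect direction and scores each copy
  separately. In the `+` copy, features with β < 0 whose association is
  *more significant* than a threshold (default 10⁻⁶) have β set to 0
  (symmetrically for `−`). Zeroing rather than removing keeps the feature
  count, hence the degrees of freedom, unchanged. The directional reading —
  zeroing what is confidently opposite rather than what is weak — removes
  the other metabolite's signal while leaving background noise alone, which
  is the quantity the split is meant to isolate; the complementary reading
  is available behind `zero_if = "less_significant"`. Each direction is
  ranked as its own sub-table.

Ranking is competition-style ("1, 1, 3"): ties share the minimal rank and
input order is preserved within ties, which is the conservative convention
when claiming "the reference metabolite ranked first". Empty-match-set
candidates rank after all scored candidates.

## Spectral databases and binning

Reference spectra carry peak lists (ppm position, height relative to the
tallest peak, which must equal 1) and/or multiplet lists (ppm range, integer
proton count). Both descriptions of one metabolite need not agree, which is
why peak and multiplet modes exist as separate settings. Databases read
from/write to a flat TSV; `read ∘ write` is the identity, and biofluid
subsets are first-class databases. Where a source lists several experimental
acquisitions per metabolite, each acquisition should be kept as its own
id-suffixed entry; the package does not attempt to reconcile them.

For simulation, spectra are rounded to a uniform grid (default 0.01 ppm over
[0, 10]). Bins are half-open `[lo + kw, lo + (k+1)w)` with boundary
positions assigned upward; when two peaks fall in one bin their heights are
summed, which conserves the spectrum size s<sup>m</sup> = Σ<sub>j</sub>
h<sub>j</sub> under any bin width — an invariant the tests exercise. ppm
values are treated as meaningful to 10⁻⁴ and compared with tolerance 10⁻⁶.

## The simulation framework

The generator emulates the essential mechanism of genetic spiking and
nothing more. Genotypes are two Bernoulli(MAF) allele draws per individual
(Hardy–Weinberg; no LD, covariates or stratification). The metabolome is

M<sub>ij</sub> = β·h<sub>j</sub>·g<sub>i</sub> + α·β·g<sub>i</sub>·a<sub>j</sub> + ε<sub>ij</sub>,  ε iid N(0, 1),

with h the binned target spectrum and a the genetic-noise support: N<sub>a</sub>
bins drawn uniformly among bins where h = 0, each with a random sign.
Restricting noise to signal-free bins is an interpretation choice: allowing
noise on the target's own bins would silently confound the target's signal
with noise amplitude, muddying the competition effect the noise term exists
to create. The noise matrix is drawn before the noise support, so setting
either N<sub>a</sub> = 0 or α = 0 reproduces the plain model bit-exactly
under a shared seed. Defaults are n = 400 individuals, MAF 0.2, 0.01 ppm
bins over [0, 10]: with these fixed, the association strength is controlled
by β alone (β is in units of the noise standard deviation per allele copy).

Association is per-bin OLS of feature on genotype; β̂ = S<sub>xy</sub>/S<sub>xx</sub>,
se = √(SSR/(n−2)/S<sub>xx</sub>), two-sided t-tail on n − 2 df. Perfect fits
(SSR = 0, possible only in degenerate toy inputs) get a standard-error floor
at machine-epsilon scale rather than an error.

Performance is summarized by r90, the 90th-percentile rank of the true
metabolite over replicates, computed as the nearest-rank order statistic
(the ⌈0.9R⌉-th sorted rank) to avoid interpolation ambiguity; r90 = 1 means
identification succeeds in at least 90% of replicates. Replicate r reseeds
the generator at `seed + r`, so single replicates are reproducible in
isolation and replicate streams are paired across configurations sharing a
base seed.

### What the synthetic database generator emulates

`generate_synthetic_db()` produces spectra with the structure of curated
reference collections: 1–6 peak clusters per metabolite at uniform positions
in [0.5, 9.5] ppm, 1–4 peaks per cluster within ±0.02 ppm, heights
renormalized to a maximum of 1, and multiplet ranges enclosing each cluster
with ~0.02 ppm padding. Two controls shape the competition structure for
experiments: `min_gap` enforces a minimum distance between all cluster
centers database-wide (large values give pairwise-disjoint match sets — the
no-competition regime), and `lead_pool` draws each metabolite's tallest
cluster from a small set of shared positions (a crowded regime where many
candidates contend for the same lead feature). It does *not* emulate real
reference collections' height profiles, J-coupling fine structure,
pH-dependent shift variability, or the mismatch between a database spectrum
and the study-specific spectrum; conclusions from passing simulation tests
therefore concern the scoring machinery, not robustness to
database–study spectral deviations.

## Problem sizes used in the checks

The replicate-simulation checks run three study designs, each a
20-metabolite synthetic database with 100 replicates per metabolite at
n = 400, MAF 0.2, δ = 0.02 in peak mode:

1. β = 1.6 on a pairwise-disjoint database (`min_gap = 0.12`, 1–3 clusters):
   with no competition and a strong signal, every metabolite attains
   r90 = 1.
2. β = 0.2 on an unconstrained database: identification is noise-limited
   and the Pearson correlation between r90 and spectrum size is negative —
   larger spectra aggregate more signal.
3. β = 1.6 with genetic noise N<sub>a</sub> = 64, α = 0.6 on a database of
   20 single-peak metabolites whose lead positions are drawn from a pool of
   five (the size-1 stratum, where the lead-peak crowding count η is an
   exact measure of the competing group): the Spearman correlation between
   r90 and η of the lead peak is positive — crowding degrades
   identification.

The single-peak design in (3) deliberately keeps the default ±0.02 ppm
cluster spread: exactly coincident lead peaks would produce identical match
sets, identical scores, and ties that competition ranking resolves to rank
1 for everyone, erasing the crowding effect the experiment measures.

Null calibration is checked on a 5-feature match set with 10⁵ iid N(0, 1)
draws of β/s: the fraction of draws with score above x is compared with
10<sup>−x</sup> within four binomial standard errors. Under the simulator's
independent-noise null this calibration is exact; under real,
correlated-feature data it is not, which is precisely why scores are ranks,
not p-values.

## Numerical and degenerate-input choices

* Scores are computed in log space throughout; they are finite for any
  finite input.
* Singular decorrelation blocks raise an error naming λ as the remedy;
  they cannot arise for λ > 0 with a valid correlation matrix.
* Monomorphic genotype draws are redrawn (bounded retries), then error.
* Constant metabolome columns are an error; zero-residual fits get an SE
  floor.
* A 2-compound self-pair equals the 1-compound candidate by construction
  (F ∪ F = F), kept in the enumeration so the pair table contains the
  1-compound table as a subset.

## Known limitations

Scores are not calibrated significance statements. The simulator's noise is
iid Gaussian per bin; real NMR noise is structured (baseline, ridges,
normalization artifacts). Peak-position mismatch between database and study
spectra — the dominant failure mode in practice — is representable only
indirectly (via δ), not generated. The CLI and file formats are
deliberately minimal; converters from vendor database dumps are out of
scope.
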