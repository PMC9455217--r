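---
title: "Merging still-image diffraction data: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Merging still-image diffraction data: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

In fixed-target serial synchrotron crystallography (SSX), thousands of
microcrystals are immobilised on a mesh chip and rastered through the
X-ray beam, one still diffraction snapshot per grid stop. Each still
records *partial* reflection intensities from one (sometimes two or
three) crystal lattices, so no single image yields usable structure-factor
amplitudes. Instead, many thousands of stills are filtered, scaled,
merged Monte-Carlo style, assessed shell by shell, and finally converted
from intensities to amplitudes. meshmerge implements that downstream
computational chain, starting from integrated per-image reflection
records (the output of a stills integrator) and ending at an amplitude
table ready for phasing. Spot finding, indexing and integration of raw
detector frames are upstream of this package and out of its scope, as
are molecular replacement and model refinement downstream.

## Symmetry engine

A reflection $\mathbf{h} = (h,k,l)$ has resolution
$d = (\mathbf{h}^{\mathsf T} G^{*} \mathbf{h})^{-1/2}$ with $G^{*}$ the
reciprocal metric tensor of the unit cell. Symmetry operators act on
reflections as row vectors, $\mathbf{h}' = \mathbf{h} R$, picking up a
phase $2\pi\,\mathbf{h}\cdot\mathbf{t}$ from the operator's translation
part. From these two facts follow everything the pipeline needs:

* **Asymmetric-unit mapping.** The canonical representative of an orbit
  (point group plus Friedel inversion) is defined here as the orbit
  member maximal under lexicographic $(h, k, l)$ ordering. This is a
  deliberate internal convention: merging only needs *some* fixed total
  order, and a self-contained rule is easier to verify by brute-force
  orbit enumeration than the zone conventions of any particular
  crystallographic suite, which we intentionally do not replicate.
* **Systematic absences.** $\mathbf{h}$ is absent iff some operator
  fixes it ($\mathbf{h}R = \mathbf{h}$) with non-integer
  $\mathbf{h}\cdot\mathbf{t}$ — the reciprocal-space signature of screw
  axes. Absences are excluded from completeness denominators by
  default; published reflection totals rarely state whether absences
  were excluded, so the flag is exposed and defaults to exclusion.
* **Centricity and epsilon.** $\mathbf{h}$ is centric iff some
  point-group operator sends it to $-\mathbf{h}$; epsilon is the order
  of its stabiliser. Both matter for intensity statistics.

Five space groups ship built in (P1, P2$_1$, P2$_1$2$_1$2$_1$,
P4$_3$2$_1$2, P6$_4$22 — the groups this pipeline is routinely used
with); arbitrary groups load from a JSON config of rotation matrices
and fractional translations
(`inst/extdata/symmetry_config_example.json`). A full space-group
library would add nothing the merging math uses.

## Outlier rejection

Three per-image filters are applied to indexed stills, mirroring
operational SSX practice: minimum spot count (default 75; small-cell
samples warrant less because fewer reflections reach the detector),
worst acceptable per-image resolution (default 2.8 Å), and maximum
fractional deviation of any refined cell length from the run average
(default 3.5%). Choices the criteria leave open, fixed here:

* *Per-image resolution* is not standardised anywhere; meshmerge uses
  the d-spacing of the rank-5 highest-resolution observation, a robust
  order statistic that ignores a handful of spurious spots. The rank is
  configurable.
* *The average cell* is computed once over all indexed lattices before
  any rejection, with crystal-system constraints re-imposed
  (symmetry-tied lengths averaged jointly). Iterative re-averaging
  changes rejection counts by well under a percent in simulation and is
  not worth the extra pass.
* *Per-criterion counts are non-exclusive*: an image failing two
  criteria increments both counters, while the rejected total counts
  unique images. Published per-criterion tallies that do not sum to the
  stated totals are consistent with this accounting.
* Cell deviation tests lengths only; angles are symmetry-fixed in all
  supported crystal systems. Multi-lattice images are rejected whole if
  any constituent lattice fails.

## Scaling and merging

The scaling model is one multiplicative factor $k_i$ per lattice — the
linear-scale Monte-Carlo approximation. Partiality post-refinement and
per-image B factors are deliberately out of scope; with the redundancy
SSX datasets reach, partiality averages out in the merge. The algorithm
alternates merging with current scales and per-lattice least squares
$k_i = \sum I_{obs} I_{ref} / \sum I_{ref}^2$ against the merged
reference, to a $10^{-6}$ relative fixed point (at most 50 iterations,
deterministic $k_i = 1$ start), then renormalises to mean 1. A
disconnected observation graph degrades gracefully: scales are
normalised per connected component with a warning, and scaling refuses
to run when no two lattices share a reflection.

Merging maps observations to the asymmetric unit and takes the
inverse-variance weighted mean of $I/k_i$ with weights
$(k_i/\sigma_I)^2$. Negative intensities are merged as-is; forcing
positivity is the job of the French–Wilson step. Half datasets for
CC$_{1/2}$ and R$_{split}$ split images by surviving-order parity
(lattices of one image stay together), which balances the halves across
the chip and across time.

## Shell statistics and the resolution cutoff

Shells are equal-volume in $1/d^3$ (default 20). Per shell the table
reports completeness against enumerated unique reflections, mean
multiplicity, mean $I/\sigma$, CC$_{1/2}$ (Pearson correlation of the
half-dataset means), R$_{split} = 2^{-1/2}\sum|I_1 - I_2| /
(\tfrac12\sum(I_1 + I_2))$, and the second moment
$\langle I^2\rangle/\langle I\rangle^2$ of merged intensities over
acentric reflections, whose Wilson expectation is 2 (centric: 3) and
which inflates with noise or twinning pathology.

The automated cutoff scans from low to high resolution and keeps shells
while CC$_{1/2} \ge 0.5$, second moment $\le 2.5$ and completeness
$\ge 90\%$; the cutoff is the $d_{min}$ of the last shell before the
first failure, and later shells are not reconsidered. The 0.5
CC$_{1/2}$ threshold is standard practice; the second-moment ceiling of
2.5 (expectation 2 plus 0.5 slack) and the 90% completeness floor are
package defaults, because the qualitative criteria this rule
operationalises ("rapidly increasing above 2", "completeness
dropping") name no numbers. All three are configurable. A metric that
cannot be evaluated in a shell (too few reflections) does not veto that
shell. The overall row of the table is computed over all unique
reflections, not averaged over shells.

## French–Wilson conversion

Merged intensities, including negative ones, convert to amplitudes via
the posterior of the true intensity $J \ge 0$ under a Gaussian
measurement model $I_{obs} \sim N(J, \sigma_I^2)$ and the Wilson prior
— acentric $P(J) \propto e^{-J/\Sigma}$, centric
$P(J) \propto J^{-1/2} e^{-J/2\Sigma}$ — with $F = \sqrt{J}$ and
$\sigma_F$ the posterior standard deviation. $\Sigma$ is the shell mean
merged intensity, floored at $10^{-6}$ of the overall mean magnitude;
shells with fewer than 10 reflections borrow the nearest populated
shell.

Rather than the historical lookup tables, the posterior moments are
evaluated by 512-node Gauss–Legendre quadrature in the amplitude
variable $u = \sqrt J$ on $[0, \sqrt{\max(I,0) + 15\sigma_I}]$. The
substitution absorbs the centric prior's integrable singularity at
$J = 0$, making the integrand smooth; results are stable to $10^{-6}$
relative under node doubling and match an independent $10^6$-node
dense-quadrature oracle to better than $10^{-4}$ in the test suite.
The strong-signal limit $F \to \sqrt I$ and monotonicity of $F$ in $I$
are verified numerically.

## Raster bookkeeping

Scan plans come from explicit grid counts or from a window size and
step (`n = floor(window/step) + 1` per axis). Image ids follow a
serpentine (boustrophedon) traversal — even rows left-to-right, odd
rows reversed — which matches stage-scan practice; the traversal is a
package convention since collection software rarely records it in the
data. Hit rates are reported to one decimal with round-half-to-even;
note that a printed hit rate can disagree with a quoted one in the
second decimal's rounding, which is why the rounding rule is pinned.

## The simulator

`simulate_run()` generates ground-truth-labelled runs with the
statistical structure the pipeline assumes, so every stage is testable
without beamline data. True intensities follow Wilson statistics with a
B-factor falloff $\Sigma(d) \propto e^{-B/2d^2}$; per grid stop a
Bernoulli draw decides a hit; hits carry 1–3 lattices; each lattice
observes a random subset of unique reflections re-expanded to random
symmetry mates, with lognormal per-lattice scales, Gaussian noise, and
fractional cell jitter; planted outlier images get shifted cells and
starved spot counts. One RNG stream with documented draw order makes
runs byte-identical under a seed.

Default parameters are chosen to emulate the regime of a real
single-chip run on a small orthorhombic protein: a 175 × 208 grid,
23.1% hit rate, 15.3%/2.5% double/triple-lattice fractions, Wilson B
of 11.5 Å², 3.5%-scale cell outliers. Two noise models are available:
`"shell"` noise proportional to $\Sigma(d)$ keeps signal-to-noise flat
across resolution (convenient for scale-recovery studies), while
`"flat"` absolute noise combined with the Wilson falloff plants a
realistic resolution-dependent signal decay for cutoff studies.

What the simulator does **not** model — and therefore what passing
tests do not demonstrate about real data: diffraction geometry and
partiality (the observation-subset mechanism stands in for partial
recording), spot shapes and mosaicity, correlated backgrounds such as
mesh fibre scatter, detector gaps, and beam drift. Conclusions about
statistical bookkeeping, scaling convergence, estimator behaviour and
threshold logic transfer; conclusions about integration quality do not.

## Numerical choices and degenerate inputs

* Scaling tolerance $10^{-6}$ relative, cap 50 iterations; a lattice
  whose least-squares scale turns non-positive (pathological noise)
  keeps its previous value for that iteration.
* Shell binning uses `findInterval` with closed right edge so boundary
  reflections land in exactly one shell; a single-reflection set is a
  valid one-shell table.
* CC$_{1/2}$ needs three usable reflections and non-degenerate
  variance; identical constant halves report 1 by convention.
  R$_{split}$ with non-positive denominator, and second moments with
  non-positive mean, are flagged `NA` rather than guessed.
* Sigma floors: observation sigmas must be strictly positive (the
  simulator floors at $10^{-8}$ of the base intensity in the noise-free
  limit); Wilson $\Sigma$ floors at $10^{-6}$ of the mean magnitude.
* Hit-rate rounding is round-half-to-even at one decimal.
* (0,0,0) is rejected as a reflection everywhere.

## Problem sizes in the shipped checks

The test suite and the acceptance script run entirely on simulated
data at desk scale, chosen as the smallest sizes at which each
statistical claim is sharp: a 50 × 50 grid with a ~230-reflection
small cell for the exact zero-noise identity; a 100 × 100 grid
(~2000 indexed stills, ~3000 unique reflections) for outlier recall,
false-flag rate and scale recovery under noise; a 40 × 40 grid with
flat noise and B = 25 Å² for the cutoff-versus-planted-decay check.
Full-chip 36400-image bookkeeping (batching, totals, hit rates) is
exercised as arithmetic, which is what it is.

## Known limitations

* No partiality or post-refinement model; datasets with low redundancy
  will merge worse than a post-refining pipeline would.
* The shipped group catalogue covers five space groups; others must be
  supplied as configs, and non-standard settings or reindexing between
  settings are unsupported.
* The hkl-text writer rounds to two decimals (fixed-width
  convention); round-trips are exact only to that precision, unlike
  the JSON-lines run format, which round-trips bit-exactly.
* Anomalous statistics (CC$_{anom}$), twin tests beyond the second
  moment, and anisotropic resolution cutoffs are not implemented.
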