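---
title: "Methods: Hi-C-constrained chromosome modelling with chromsteer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Hi-C-constrained chromosome modelling with chromsteer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

chromsteer implements a knowledge-based pipeline for modelling interphase
chromosome organization: statistically significant cis-chromosome contacts
are selected from Hi-C count matrices, imposed as steered centre-of-mass
restraints on a coarse-grained polymer model of the diploid genome confined
in a spherical nucleus, and the resulting conformations are analysed for
restraint compliance, radial organization, macrodomain structure, and
pre-mitotic recondensation behaviour. This vignette records the models, the
tunable parameters, and the design decisions, in enough detail that every
number the package produces can be traced to a stated assumption.

## Contact calling

### The background model

Hi-C cis-contact counts $x_{ij}$ at 100 kb resolution are sparse and
over-dispersed. At fixed genomic distance $\delta = |i - j|$ (in bins) the
count distribution is modelled as a zero-inflated negative binomial (ZiNB):

$$P(X = 0) = \pi + (1-\pi)\,\mathrm{NB}(0;\theta,\mu), \qquad
  P(X = k) = (1-\pi)\,\mathrm{NB}(k;\theta,\mu), \; k > 0,$$

with $\mathrm{NB}(k;\theta,\mu) =
\frac{\Gamma(k+\theta)}{\Gamma(\theta)\,k!}
\left(\frac{\theta}{\theta+\mu}\right)^{\theta}
\left(\frac{\mu}{\theta+\mu}\right)^{k}.$

Here $\pi$ is the probability of an excess (structural) zero, $\theta$
captures extra-Poisson variance, and $\mu$ is the NB mean. Internally the
NB is parametrized by $(\theta, \mu)$ for numerical stability; the
classical failure probability is recovered exactly as
$p = \theta/(\theta+\mu)$.

Each distance is fitted separately (`fit_zinb()`), by direct numerical
maximum likelihood: BFGS on $(\mathrm{logit}\,\pi, \log\theta, \log\mu)$
from a moment-based start, with two fallback starts, a sloped penalty
outside generous parameter bounds, and standard errors from the inverse
observed information (delta method back to the natural scale). Distances
with fewer than 50 observations or fewer than 10 nonzero values are pooled
with neighbouring distances until both thresholds are met (status
`"pooled"`); all-zero groups are `"degenerate"` and yield no tests.
Structural zeros between unmasked bins are observations, not missing data,
and enter every fit.

### Robustness: upper-censored likelihood

A background fit on real data always contains the enriched contacts one is
trying to detect. A plain ZiNB MLE is not robust to them: a few strongly
enriched pairs per distance drive $\hat\theta$ down until the fitted tail
covers the signal itself, and the tail test loses essentially all power.
`call_contacts()` therefore fits with an *upper-censored* likelihood
(`censor_q = 0.15` by default): the top 15% of observations in a distance
group contribute $P(X > c)$ — with $c$ the empirical 85% quantile — rather
than their pmf. The censored estimator remains consistent when the model
holds (censoring is modelled, not ignored), loses only modest efficiency,
and keeps its breakdown point above the enrichment fractions a desk-scale
matrix can carry. Censoring disables itself when the cutoff would fall
below 2 counts, where it would destroy the information in sparse groups.

### Bias correction and the testing scale

`ice_normalize()` implements iterative correction: per-bin multiplicative
bias factors are iterated until all unmasked marginals are equal;
zero-marginal bins are masked from balancing and from every downstream
test. Bias estimation is made robust to focal signal by per-distance
clipping of the highest entries (`high_frac`) while the factors are
iterated — strongly enriched contacts otherwise masquerade as per-bin
visibility bias — and the final factors are applied to the unclipped
matrix, rescaled to preserve the total count.

Which scale to *test* on is a real decision. Dividing counts by estimated
bias products is only harmless when the bias estimates are precise. On a
matrix with a few hundred bins each marginal is estimated from of order a
hundred over-dispersed counts (roughly 30% relative error), so corrected
entries become a scale mixture: corrected-scale testing then runs several
times above its nominal false-discovery level, with the false positives
concentrated on pairs whose correction factors are largest. Testing raw
counts per distance, by contrast, stays calibrated at the nominal level
(the acceptance script measures this directly), because with a separate
fit at every distance a
multiplicative visibility bias enters only the per-pair mean and is
absorbed into the per-distance dispersion. `call_contacts()` therefore
defaults to `test_on = "raw"`; `test_on = "corrected"` (rounded to the
nearest integer, preserving the discrete model's support) is available and
appropriate when bins are numerous enough for precise bias estimates.

### Selection

The upper-tail p-value of an observed count is
$P(X \ge x) = (1-\pi)\,(1 - F_{\mathrm{NB}}(x-1))$ for $x \ge 1$ and
exactly 1 for $x = 0$. Multiple testing is corrected *at fixed distance*:
the Benjamini–Hochberg step-up procedure is applied separately within each
$\delta$ group at level $\alpha = 0.01$ (1% FDR), and the union over
distances is reported. Self-interactions ($\delta = 0$) are never tested;
`min_delta` defaults to 1 bin.

Under the package's own synthetic conditions (twenty 100-bin matrices, 200
planted fold-50 contacts each — an enrichment density orders of magnitude
above real data) the test suite checks that the mean false-discovery
proportion stays at the nominal 1% level within Monte-Carlo error and that
the power against planted contacts exceeds one half; the acceptance script
recomputes the false-discovery proportion from scratch.

## The polymer model

### Force field and units

Chromosomes are bead-spring chains: bead diameter $\sigma = 30$ nm, one
bead per 3,030 bp (so a 100 kb bin spans 33 beads and a 200 kb spacing 66
beads). Energies are in $k_BT$ ($\epsilon = k_BT = 1$), lengths in nm, and
the intrinsic time unit is $\tau_{LJ} = \sigma\sqrt{m/\epsilon}$ with
$m = 1$. The force field is the standard Kremer–Grest set:

* FENE bonds, $K = 30\,\epsilon/\sigma^2$, $R_0 = 1.5\sigma$;
* WCA excluded volume (purely repulsive LJ, cutoff $2^{1/6}\sigma$),
  cell-list accelerated;
* Kratky–Porod bending $U = \kappa(1-\cos\theta)$ with
  $\kappa = 5\,\epsilon$, targeting a persistence length of
  $5\sigma = 150$ nm. For the discrete chain
  $\langle\cos\theta\rangle = \coth\kappa - 1/\kappa \approx 0.800$,
  equivalent to an ideal-chain decay length of 134.5 nm; excluded-volume
  swelling raises the *measured* tangent-correlation decay above that
  ideal value, toward the 150 nm target (the acceptance run measures it on
  free chains);
* a confining harmonic wall active beyond $R_{nuc} - \sigma/2$ with a
  force cap (1 $\epsilon$/nm), whose capped branch doubles as the radial
  compressive force that returns protruding beads;
* an attractive cut-shifted LJ (depth 1 $\epsilon$, cutoff $1.5\sigma$)
  between centromeric beads of the same chain, which compacts centromeres
  during relaxation.

The nucleus is a sphere of radius 4,800 nm; the diploid genome carries two
copies of each autosome and a single X (no Y).

### Integration

Dynamics are underdamped Langevin, integrated with the BAOAB splitting at
$\Delta t = 0.012\,\tau_{LJ}$ and friction $\gamma = 0.5/\tau_{LJ}$.
BAOAB samples the configurational distribution with small step bias (a
three-bead angle test reproduces $\langle\cos\theta\rangle$ to three
digits), reduces exactly to velocity Verlet in the NVE limit, and obeys
equipartition and the Einstein relation within the tolerances asserted in
the test suite. Two guards catch instability: a FENE bond reaching $R_0$
and a per-half-step displacement exceeding $\sigma$ both abort the run.

Dense prepared conformations (stacked rosettes, interpenetrating coils)
cannot be started under the exact excluded volume. All protocols therefore
begin with a short *push-off* phase: pair forces accumulate separately and
the net pair force per bead is capped, with the cap ramped (2, 5, 10, 20
$\epsilon$/nm), a small step (0.002 $\tau_{LJ}$), high friction
(20 $/\tau_{LJ}$) and a 0.5 nm per-step displacement clamp. Capping the
*net* per-bead pair force (not per pair) guarantees that no crowding can
out-pull a FENE bond. The compression phase likewise runs strongly damped
($\gamma = 5/\tau_{LJ}$, displacement clamp 2 nm): beads falling toward the
nucleus from far outside must not pick up supra-thermal kinetic energy
before entering the crowded interior.

### Genome building

Each chain starts as a rod-like stack of rosette petals, laid with exact
$\sigma$ spacing along a rosette curve (petals of `n_loop` beads,
`n_petals` per turn, axial pitch per turn). The defaults
(`n_loop = 100, n_petals = 12, pitch = 2` $\sigma$) give lengthwise-compact
rods whose length grows linearly with bead number; note that strong
prolateness (asphericity > 0.8) requires chains long enough to span many
rosette turns — short chains of a few petals are necessarily disc-like,
which is a geometric fact, not a tunable.

Placement is longest-first with random orientation. Random mode draws the
midpoint uniformly in the nuclear volume and keeps the first placement
without trans steric clashes (no inter-rod bead pair closer than
$\sigma$; clash checks use a cell grid). Phenomenological mode draws the
midpoint inside the equal-volume radial shell (of six) containing the
chromosome's target mean radial position and keeps, among non-clashing
candidates, the one minimizing |mean bead radius − target|, reporting the
residual. Equal-volume shells were chosen over equal-thickness because
they give uniform prior occupancy under random placement. The trial
optimisation is per-chromosome within the sequential placement; a
genome-wide restart scheme would be combinatorially unaffordable and the
sequential reading matches how clash rejection must operate anyway.

Relaxation (`relax()`) evolves the compressed system — 120,000
$\tau_{LJ}$ at production scale — while centromeres compact and arms
expand. Desk-scale runs shorten all durations through `time_scale`; the
vignette's and test suite's problem sizes (chains of a few hundred to a
few thousand beads, tens to hundreds of $\tau_{LJ}$) are chosen so every
qualitative claim remains measurable on a single CPU. `coil_system()`
provides the desk-scale stand-in for the fully relaxed state: chains drawn
from the equilibrium discrete Kratky–Porod angle distribution, grown
confined inside the nucleus, so orientational statistics start at
equilibrium and only excluded-volume swelling remains to relax.

## Steering

Each significant contact (a 100 kb bin pair) becomes a harmonic restraint
between the centres of mass of the two 33-bead target regions, duplicated
in each homolog copy — a cis contact never couples homologs. The
equilibrium distance is 0 (pure attraction): the paper-level notion of
"contact" is judged by the analysis cutoffs, not by the spring's minimum.

Initial spring constants are entropy-matched: the stiffness that just
counteracts the entropic recoil of the intervening chain segment, taken as
the worm-like-chain entropic spring constant

$$k_{init}(s) = \frac{3 k_B T}{2\, l_p\, L(s)}, \qquad L(s) = s\,\sigma,$$

with $s$ the sequence separation in beads (so $k_{init}(2s) =
k_{init}(s)/2$; separations below 66 beads — the 100 kb region scale —
are clamped with a warning). During steering each spring ramps linearly to
`k_max` (default 0.1 $k_BT$/nm²) over the run; production steering lasts
at most 6,000 $\tau_{LJ}$. The restraint force on each COM pair is capped
(default 1 $k_BT$/nm, i.e. about 0.03 $k_BT$/nm per member bead): a bare
harmonic at ramped stiffness over micron-scale distances would otherwise
exceed the force scale the bonded structure can transmit. A second
restraint set can be added after steering
(`add_restraints_and_continue()`, production cap 600 $\tau_{LJ}$): the
old set is held at full stiffness while the new set ramps from its own
entropy-matched start, and the maintained fraction of the old set and
established fraction of the new set are reported.

## Recondensation

The pre-mitotic recondensation protocol (`recondense()`) removes all
steering restraints and couples single-bead loci at a regular 66-bead
(200 kb) spacing along each chain, the last bead always anchored so every
segment is covered. All spring constants are equal and constant (default
1 $k_BT$/nm²). The equilibrium distances step down from 200 nm (the
maximum extension of a 200 kb model strand) to 30 nm (one bead) every
0.6 $\tau_{LJ}$; because a 30 nm decrement does not divide the 170 nm span
evenly, the schedule is 200, 170, 140, 110, 80, 50, 30 — the final step is
20 nm so the protocol lands exactly on the bead size, which takes priority
over step uniformity. At the terminal distance the run extends to
300 $\tau_{LJ}$. Satisfaction of the loop couplings is reported per
snapshot with the same criteria and cutoffs as steering; comparing runs
started from steered versus merely relaxed conformations measures how much
the steered organization obstructs recondensation (it should not, and in
the package's toy systems the two final compliances agree within a few
percentage points).

## Structure analysis

* **Satisfaction** — a restraint is satisfied under the COM criterion when
  the distance between region centres of mass is at most the cutoff, and
  under the closest-bead criterion when the minimum over all bead pairs
  is; cutoffs 120, 240, 480 nm. Closest-bead dominates COM at equal
  cutoff, and fractions are monotone in the cutoff, by construction.
* **Distance matrices** — conformations are coarse-grained to 100 kb by
  averaging the 33 bead positions per bin; Euclidean distances between bin
  means.
* **Kendall association** — tie-corrected Kendall $\tau_b$ (via
  `stats::cor.test`) between corresponding upper-triangle entries of the
  model distance matrix and the Hi-C count matrix, restricted to pairs
  with genomic separation above a sweep of thresholds; the expected
  association is negative (closer in space, more reads). Thresholds with
  fewer than 10 pairs are flagged and omitted.
* **Radial profiles** — 15 equal-thickness shells over $[0, R_{nuc}]$
  (320 nm each at the default radius); per shell and feature, the
  percentage of shell beads carrying the feature, aggregated over
  replicate conformations; per-100 kb-bin mean and standard deviation of
  radial position across replicates are also returned. Empty shells yield
  `NA`, never 0.
* **Macrodomains** — the dissimilarity between 100 kb segments is the
  replicate-averaged distance when below 750 nm and 1,000 nm otherwise
  (the asymmetric gap is deliberate and kept as stated); each chromosome
  arm is partitioned separately into a requested number of
  sequence-contiguous domains minimizing total within-domain dissimilarity
  to the best medoid segment. The optimum is found exactly by dynamic
  programming over block boundaries with first-minimum tie-breaking, so
  results are deterministic; the test suite verifies equality with an
  exhaustive boundary enumeration on all instances up to 15 segments.
* **Overlap** — the overlap $q$ of two partitions is the fraction of
  segments whose sequentially numbered domain labels agree (centromeric
  segments excludable). Significance compares $q$ against random
  sequence-continuous subdivisions of the same arms into the same domain
  counts, boundaries uniform over placements:
  $p = (1 + \#\{q_{rand} \ge q\})/(n_{rand}+1)$. Randomizing one
  partition against a fixed reference makes the p-value exactly
  super-uniform when both partitions are unrelated.
* **Procrustes RMSD** — optimal translation + rotation (Kabsch/SVD, no
  scaling by default; `scale = TRUE` optional) minimizing the RMSD of
  matched point sets.
* **MDS reconstruction** — contacts convert to distances
  $d_{ij} = x_{ij}^{-\alpha}$ (default $\alpha = 1$; the exponent is a
  convention, exposed in the call), missing entries are completed to the
  shortest-path metric (graph distances, equivalent to Floyd–Warshall),
  and classical MDS (top three eigenvectors of the double-centred squared
  distance matrix) returns 3D coordinates.

## The synthetic generator

`gen_genome_spec()` and `gen_hic_matrix()` exist so the whole pipeline is
testable without external data. The matrix generator draws every
background pair at distance $\delta$ from ZiNB$(\pi, \theta, \mu_\delta)$
with a power-law decay $\mu_\delta = c/\delta$ (defaults $\pi = 0.3$,
$\theta = 2$, $c = 100$ — a realistic sparsity and depth for 100 kb cis
matrices; the decay form is a convention, exposed in the constructor).
Planted pairs draw from the same NB family with the mean multiplied by
their fold enrichment and zero inflation suppressed; default planted
separations span 200 kb to half the chromosome, mimicking a mixture of
local and long-range constraint sets. The generator emulates sparsity,
distance decay, zero inflation, and focal enrichment; it does *not*
emulate restriction-fragment bias, copy-number variation, trans contacts,
or correlated neighbourhoods around enriched pairs — so a passing
pipeline demonstrates statistical calibration and recovery under the
stated model, not robustness to every artefact of real libraries.
Annotation tracks carry a configurable monotone gene-density gradient with
LAD blocks complementary to gene blocks, enough to exercise the radial
enrichment machinery with a known planted spatial signal.

## Known limitations

* Desk-scale durations cannot reproduce production-scale relaxation;
  `coil_system()` is an equilibrium stand-in, not a simulated relaxation
  product.
* The recondensation schedule's real-time mapping (hours per
  $\tau_{LJ}$) is outside scope; all times are in reduced units.
* Corrected-scale testing should be preferred only on matrices large
  enough for precise bias estimates (see above); the package does not
  switch automatically.
* The nucleus is spherical; flattened ellipsoidal geometries are not
  implemented.
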