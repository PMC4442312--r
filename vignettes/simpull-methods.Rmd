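---
title: "Quantifying single-molecule pull-down experiments: models and methods"
author: "SiMPullCount authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying single-molecule pull-down experiments: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(SiMPullCount)
```

## The assay and what this package computes

Single-molecule pull-down (SiMPull) immunoprecipitates protein complexes
from cell lysate onto a passivated, antibody-coated slide surface and images
them one complex at a time by total internal reflection fluorescence (TIRF)
microscopy. Each surface-tethered complex appears as a diffraction-limited
spot. Three quantitative readouts follow:

1. **Molecule counting.** The number of fluorescent molecules per imaging
   area (5000 µm² here), averaged over replicate areas with the standard
   deviation across areas as the error bar. A mock pull-down with an
   irrelevant antibody gives the nonspecific background, and the
   sample-to-control ratio is the specificity check. Lysates are diluted to
   a countable density; multiplying counts by the dilution factor puts
   conditions on a common per-volume scale.
2. **Stoichiometry by photobleaching.** Under continuous excitation each
   fluorescent-protein tag bleaches in a single irreversible step, so a
   spot's intensity trajectory is a descending staircase whose step count
   equals the number of fluorescent tags in that complex. The population
   histogram of step counts reports the subunit copy-number distribution.
3. **Two-color colocalization.** With two prey proteins labeled in
   different colors, the fraction of spots of the *lower-density* channel
   that have a partner spot within 2 pixels (≈ 300 nm at 150 nm/pixel, one
   diffraction-limited spot) estimates the co-complex fraction — the
   probability that one bait molecule carries both labeled partners.

Every stage is implemented against a synthetic TIRF-field generator with
full per-molecule ground truth, so the package's accuracy claims are
parameter-recovery measurements, not appeals to plausibility.

## The generative model

`SimulationConfig()` / `simulateField()` simulate one field of view:

* **Geometry.** 471 × 471 pixels at 150 nm/pixel ≈ 5000 µm², one imaging
  area per field; replicate areas are independent seeds. The pixel size is
  chosen so that the conventional 2-pixel colocalization criterion equals
  the ≈ 300 nm diffraction limit.
* **Molecules.** Specific complexes arrive as a spatial Poisson process
  with intensity `surfaceDensity` (default 0.02 /µm², ≈ 100 per area — a
  typical "optimal single-molecule density"). Each complex carries a
  channel-A label with a copy number drawn from `copyNumberDist`
  (default monomeric).
* **Maturation.** Each labeled subunit independently carries an *active*
  chromophore with probability `maturationProb` (default 0.75, a
  conventional estimate for YFP-class fluorescent proteins; an assumption,
  not a measurement). Non-matured tags are dark and cause undercounting —
  the package models this explicitly rather than ignoring it.
* **Photophysics.** An active fluorophore emits `unitIntensity` photons per
  frame (default 100) spread by a pixel-integrated Gaussian PSF
  (`psfSigmaPx` = 1 px ≈ 150 nm, a standard visible-light TIRF
  approximation) and survives each frame with probability
  `1 − bleachProbPerFrame`. Geometric (memoryless) survival is the
  discrete-time form of exponential bleaching kinetics. No blinking is
  simulated by default; the step fitter treats upward jumps as a rejection
  category instead.
* **Camera.** Pixel values are Poisson(signal + `backgroundLevel`) plus
  Gaussian read noise (`readNoiseSd`), clipped at zero; gain is fixed at 1
  so all intensities are in photon units.
* **Two-color structure.** Every specific complex carries the channel-A
  (bait-partner) label; a fraction `coComplexFraction` also carries a
  channel-B partner at the same surface position. An independent
  channel-B-only population (`partnerOnlyDensity`, default equal to
  `surfaceDensity`) models the second prey being pulled down independently
  and in excess — the situation in which the lower-density channel is the
  bait-partner channel and its colocalization percentage estimates the
  co-complex fraction. Channel B can be misregistered by `channelOffsetPx`.
* **Background binders.** Nonspecific monomeric spots at
  `nonspecificDensity` (default 0.002 /µm², one tenth of the specific
  density) model the low mock-antibody background.

**Movie length and illumination.** Frame counts and exposure are not
physical constants of the assay; they are acquisition choices. Two regimes
are used throughout:

* *Photobleaching movies*: 400 frames at `bleachProbPerFrame = 0.01`, so
  ≈ 98 % of fluorophores bleach within the movie (the simulator reports the
  unbleached fraction).
* *Counting acquisitions*: 12 frames at `bleachProbPerFrame = 0.001`.
  Counting and colocalization only use the detector's 10-frame average
  projection, and a molecule that bleaches in the first frames of a long
  movie is invisible to any projection-based detector; real experiments
  likewise count molecules from short, low-dose acquisitions taken before
  the bleaching run.

### What the generator does not emulate

No stage drift, focus change, uneven TIRF illumination, EM-gain noise
statistics, fluorophore blinking, or FRET. Passing recovery tests therefore
show that the algorithms are correct under the stated noise model — they do
not show robustness to drift or blinking, which real data may require.

## Spot detection and counting

`detectSpots()` averages the first `projectionFrames` (10) frames, estimates
the background as the median of the projection and its noise as
1.4826 × MAD (robust to the spots themselves), and keeps local 8-neighbor
maxima above `background + thresholdFactor × sd` (threshold factor 5; a
Gaussian 5σ tail keeps false spots below about one per field). Maxima closer
than `minSeparationPx` (3 px) merge to the brighter one, and positions are
refined to subpixel accuracy by the intensity-weighted centroid of the
(border-clipped) 5 × 5 neighborhood — sufficient localization for a 2-pixel
match criterion; full PSF fitting is deliberately out of scope.

Counting linearity is validated by regressing measured counts on the
per-field ground-truth counts across expected densities of 50–500 molecules
per area (8 fields per density). The residual few-percent loss is dominated
by pair merging below the 3-px separation limit — the onset of the overlap
regime, which grows quadratically with density and is the reason lysates
are diluted to ~100 molecules per area in practice.

## Trace extraction and step counting

`extractTrace()` performs aperture photometry: the per-frame value is the
sum over a 3-px-radius aperture minus the aperture area times the median of
a 5–7 px background annulus. `countSteps()` fits a piecewise-constant
staircase by greedy binary segmentation with coordinate-descent refinement:
change points are inserted at the split that most reduces the residual sum
of squares, each insertion followed by re-optimizing every change point
with the others fixed, and insertion continues only while

RSS + `penalty` · σ² · k · log T

decreases (k = step count, T = trace length, σ a robust noise estimate from
the trace's first differences, `penalty` = 2 — two parameters, location and
level, per change point; a Schwarz/BIC-type criterion). Steps smaller than
`minStepSize` (default 3σ, the conventional significance floor — spurious
steps are the penalty's job, the floor only removes sub-noise steps) and
plateaus shorter than `minDwellFrames` (3) are pruned.

A trace is **accepted** only if all retained steps are downward and the
final plateau is within 3σ of zero (complete bleaching), so step counts are
complete counts. Everything else is rejected with a reason —
`no_full_bleach`, `upward_step` (blinking-like events are rejected, not
repaired), `too_many_steps` (more than `maxSteps` = 5), or `low_snr` — and
`buildStepDistribution()` conserves traces exactly: accepted + rejected =
input.

`oracleStepFit()` is the validation oracle: an exact dynamic-programming
search equivalent to brute-force enumeration of all change-point placements
(quadratic in T). On staircases with 1–3 steps at step:noise ratio 5 the
greedy fit attains the exact optimum RSS and recovers the exact step count
in ≥ 99 % of traces; recovery is defined against *resolvable* bleach events
(distinct frames, dwells at least `minDwellFrames`) because two fluorophores
bleaching in the same frame produce one physical step. Below step:noise ≈ 3
undercounting grows and results should be treated as qualitative; the
rejection tallies make the discard rate visible rather than hiding it.

## Stoichiometry with dark-fraction correction

With maturation probability m, a complex with n labeled subunits shows j
observable steps with probability

P(j | n, m) = C(n, j) mʲ (1 − m)ⁿ⁻ʲ / (1 − (1 − m)ⁿ),  j = 1..n,

conditioned on the complex being visible at all (`visibleStepPmf()`).
`inferStoichiometry()` fits maximum-likelihood mixture weights over
n = 1..`nMax` (default 4) to the observed step histogram by
expectation–maximization (weights-only EM on a multinomial mixture — the
log-likelihood is concave in the weights; 10 restarts from random
Dirichlet draws guard the boundary, under a local seed so the caller's RNG
stream is untouched). The dominant-species call lists every n with weight
≥ 0.1, so a minor two-copy population is reported as a real species
("monomer + dimer") rather than averaged away. Fitting at m = 1 reads the
histogram raw; both the corrected and raw fits are reported by the
pipeline, since published step histograms are conventionally read without
an explicit maturation correction. Joint inference of m from the data is a
non-goal: it requires calibration constructs the assay does not provide.

For colocalization, a monomeric partner with maturation m is invisible with
probability 1 − m, so the observed co-complex fraction underestimates the
truth; `coComplexFractionCorrection()` divides by m and caps at 1.

## Colocalization

`colocalize()` matches spots one-to-one (candidate pairs within the radius,
assigned greedily closest-first, ties broken by spot index, each spot used
once — preventing double counting without needing optimal assignment at
SiMPull densities) and divides matched pairs by the lower-density channel's
count, per field; fields aggregate as mean ± s.d. (n − 1).
`expectedChanceColocalization()` reports the Poisson-null expectation
100 × (1 − exp(−λπr²)) for the denser channel's density λ; it is reported
alongside but *not* subtracted by default, matching how raw percentages are
conventionally published (subtraction is available to the caller). The
null formula describes an infinite plane, so its Monte-Carlo validation
samples reference spots away from the field border. `compareConditions()`
turns two replicate sets into a difference, ratio and two-sample z-score —
the scaffold-loss readout for comparing, e.g., control and knock-down
lysates.

## Pipeline, determinism and problem sizes

`runPipeline()` executes simulate → detect → quantify (+ control
comparison) → trace → step counting → stoichiometry → colocalization from
one hierarchical configuration (YAML via `readRunConfig()`), streaming one
field at a time because a 400-frame two-channel field occupies ~1.4 GB.
All module defaults are overridable and the fully resolved configuration,
its MD5 hash and the seed are embedded in the JSON report; the same
configuration and seed reproduce the report byte-identically. Every
random draw descends from the configured seed via fixed integer
derivations, so replicate fields are independent but reproducible.

Validation problem sizes (chosen to give stable statistics on a single
CPU in minutes): 500 traces per step-count condition; 150 traces against
the exhaustive oracle at 300 frames; 1000 traces per stoichiometry
population; 20 imaging areas per colocalization condition at ~100
complexes each; 8 fields per density for counting linearity; 100
replicate field pairs for specificity. The packaged step-counting demos
use three half-area (2494 µm²) fields — counts are rescaled to the
5000 µm² reference area regardless.

## Known limitations

* Overlap (density > ~500 molecules per area) causes sublinear counting;
  the simulator refuses configurations beyond half a molecule per pixel.
* The maturation default (0.75) is a literature-conventional assumption;
  stoichiometry weights shift accordingly if the true maturation differs.
* Rejection fractions depend on movie length relative to bleaching rate;
  traces that do not bleach to background within the movie are discarded,
  which biases against very high copy numbers in short movies.
* The channel offset is a configuration input; estimating an affine map
  from fiducials is out of scope.
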