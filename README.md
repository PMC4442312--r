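# SiMPullCount

Quantitation of single-molecule pull-down (SiMPull) experiments in R.

SiMPull immunoprecipitates protein complexes from cell lysate onto a
passivated, antibody-coated slide surface and images them one complex at a
time by TIRF microscopy. A million cells suffice where ensemble co-IP needs
grams of pellet — but the images only become biology through careful
quantitation. This package implements that quantitation for experimentalists
and image analysts:

* **Molecule counting** — diffraction-limited spot detection on the early-
  frame average projection, molecules per imaging area (5000 µm²) with
  across-area error bars, antibody-control specificity ratios, and dilution
  normalization for comparing differently diluted lysates.
* **Subunit stoichiometry** — aperture photometry traces, photobleaching
  step counting by penalized change-point staircase fitting, and
  maximum-likelihood inference of the copy-number mixture with an explicit
  correction for non-matured (dark) chromophores: a complex with *n* labeled
  subunits whose tags mature with probability *m* shows *j* bleaching steps
  with probability
  *P(j | n, m) = C(n, j) mʲ(1−m)ⁿ⁻ʲ / (1 − (1−m)ⁿ)*.
* **Two-color colocalization** — one-to-one spot matching within 2 px
  (≈ 300 nm), the colocalization percentage with the lower-density-channel
  denominator, the Poisson chance-overlap null
  *100 × (1 − exp(−λπr²))*, dark-partner correction
  (*true = observed / m*), and condition comparison with z-scores (the
  scaffold-loss readout).
* **A synthetic TIRF-field simulator** — surface complexes as a spatial
  Poisson process, per-subunit chromophore maturation, geometric
  photobleaching, Gaussian PSF rendering, Poisson shot noise plus read
  noise, nonspecific background binders, and two-channel co-complex
  structure — with full per-molecule ground truth, so every pipeline stage
  is validated by parameter recovery rather than by eye.

## Worked example

Simulate one pull-down field in which 20 % of complexes carry two labeled
copies of the prey (maturation 0.75), then count, trace, and infer
stoichiometry:

```r
library(SiMPullCount)

cfg <- SimulationConfig(fieldWidthPx = 333, fieldHeightPx = 333, nFrames = 400,
                        surfaceDensity = 0.02, copyNumberDist = c(0.8, 0.2),
                        maturationProb = 0.75, seed = 42)
fld <- simulateField(cfg)

spots <- detectSpots(stacks(fld)$A)
quantifyFields(list(spots), fieldAreaUm2 = fieldAreaUm2(cfg))
#> FieldQuantification [A]: 94.2 +/- NA molecules per 5000 um^2 (n = 1 areas)

stk  <- stacks(fld)$A
fits <- lapply(seq_len(nrow(spots)), function(i)
    countSteps(extractTrace(stk, spots[i, ])))
dist <- buildStepDistribution(fits)
dist
#> StepDistribution: 37 accepted, 2 rejected
#>   steps: 1:33  2:4
#>   rejected: no_full_bleach:2

inferStoichiometry(dist, m = 0.75)
#> StoichiometryEstimate (maturation = 0.75 ):
#>   weights: n=1:0.820  n=2:0.180  n=3:0.000  n=4:0.000
#>   call: monomer + dimer | logLik: -12.67
```

Reading the output: 94 molecules per 5000 µm² imaging area is in the
optimal counting regime; 37 traces bleached completely and entered the step
histogram (2 never reached background and were rejected, not silently
dropped); the 33:4 one-step:two-step split, seen through the binomial
dark-fraction model at m = 0.75, yields a copy-number mixture of 82 %
single-copy and 18 % two-copy complexes — the "monomer + dimer" call — close
to the generating 80/20 truth.

End-to-end runs are driven by one YAML configuration
(`runPipeline("config.yaml", outDir = "out")`); packaged examples live in
`inst/extdata/demo_*.yaml`, and `inst/scripts/simpull.R` wraps the same
functions as a `simulate|detect|steps|stoich|coloc|run` command line.

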