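# Pull-down in which 20% of complexes carry two labeled copies of the prey
# (80% one copy), maturation 0.75. Expected readout: a mixed one-/two-step
# distribution and a "monomer + dimer" stoichiometry call.
label: demo-dimer-mix
seed: 102
nFields: 3
simulation:
  fieldWidthPx: 333
  fieldHeightPx: 333
  nFrames: 400
  surfaceDensity: 0.02
  copyNumberDist: [0.8, 0.2]
  maturationProb: 0.75
  bleachProbPerFrame: 0.01
  nonspecificDensity: 0.002
stoichiometry:
  maturation: 0.75
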