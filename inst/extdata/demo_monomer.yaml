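# Monomeric bait-prey pull-down: both channels monomeric, every bait complex
# carries a labeled partner (co-complex fraction 1), maturation 0.75.
# Expected readout: a predominantly one-step photobleaching distribution and
# a "monomer" stoichiometry call.
label: demo-monomer
seed: 101
nFields: 3
simulation:
  fieldWidthPx: 333
  fieldHeightPx: 333
  nFrames: 400
  surfaceDensity: 0.02
  maturationProb: [0.75, 0.75]
  bleachProbPerFrame: 0.01
  nChannels: 2
  coComplexFraction: 1.0
  nonspecificDensity: 0.002
stoichiometry:
  maturation: 0.75
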