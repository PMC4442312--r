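# Two-color co-complex readout, control condition: co-complex fraction 0.4.
# Counting acquisition: short movie at low excitation dose.
label: demo-scaffold-control
seed: 103
nFields: 20
simulation:
  nFrames: 12
  surfaceDensity: 0.02
  maturationProb: [1.0, 1.0]
  bleachProbPerFrame: 0.001
  nChannels: 2
  coComplexFraction: 0.4
  partnerOnlyDensity: 0.02
  nonspecificDensity: 0.0
steps:
  run: false
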