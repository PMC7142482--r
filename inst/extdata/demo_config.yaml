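# Demo pipeline configuration: a 4-cell-line cohort (cell extracts, 3
# replicates each) with planted 3-fold effects in U118, quantified against
# the 12-metabolite built-in library and fed into ANOVA/PCA statistics and
# a TCA-fragment flux comparison of two protein-presence contexts.
seed: 11
outputDir: nmrflux_demo_out
simulate:
  nMetabolites: 12
  gridPoints: 4096
  groups:
    - {cellLine: LN18, sourceType: cell}
    - {cellLine: A172, sourceType: cell}
    - {cellLine: U118, sourceType: cell}
    - {cellLine: NHA, sourceType: cell}
  replicates: 3
  baseConcentration: 1.0
  effects:
    U118.cell: {lactate: 3.0, choline: 3.0}
  biologicalCV: 0.1
  noiseSd: 0.0005
  shiftJitterSd: 0.0
  baselineAmp: 0.0
preprocess:
  normalization: none
  alignment: none
quantify:
  plsComponents: 10
stats:
  labels: cellLine
  anovaThreshold: 5
  pcaComponents: 2
  corrDiff:
    groupA: {cellLine: [LN18]}
    groupB: {cellLine: [U118]}
  ora:
    gmt: pathways_demo.gmt
flux:
  network: mini_tca
  cutoff: 50
  objectiveFraction: 0.9
  contexts:
    LN18: [aco, idh, ogdh, sdh, fh]
    U118: [aco, idh, ogdh]
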