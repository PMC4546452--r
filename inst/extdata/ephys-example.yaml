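# Synthetic slice-experiment configuration (young-animal parameterization,
# shortened epochs for a quick demonstration)
noiseSd: 0.0177
baselineMinutes: 5
postMinutes: 15
ioRepeats: 2
ptpPercent: 206.1
ltpPlateauPercent: 160.2
ptpDecayTau: 10
facilitationFactor: 1.58
afpTrainScaling: [1.0, 1.35, 1.55, 1.61]
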