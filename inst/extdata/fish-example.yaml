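# Per-cell fluorescence for glutamine synthetase in young animals
nCells:
  astrocyte: 500
  neuron: 250
conditions: ["C", "CS", "LTP", "LTP BAY"]
foldChange:
  CS:  {astrocyte: 4.33}
  LTP: {astrocyte: 7.94}
  "LTP BAY": {astrocyte: 2.21}
backgroundMean: 50
backgroundSd: 5
controlSignalMean: 100
cellNoiseSd: 15
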