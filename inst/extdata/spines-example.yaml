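# Two spine populations: basal-stimulated control vs 90 min post induction
groups:
  - nSpines: 400
    conditionLabel: "CS 90"
    lengthLogmean: 0.0316    # mean length-to-width ratio ~ 2.87
    nSlices: 7
  - nSpines: 400
    conditionLabel: "LTP 90"
    lengthLogmean: -0.413    # mean length-to-width ratio ~ 1.84
    nSlices: 12
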