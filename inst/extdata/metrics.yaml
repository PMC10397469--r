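# Metric and anchor definitions for the MID pipeline.
# direction_of_benefit: +1 if an increase is improvement, -1 if a decrease is.
# icc: test-retest reliability used for the SEM / minimal detectable change.
metrics:
  rvef:
    label: RVEF
    units: "%"
    direction_of_benefit: 1
    icc: 0.94
  rvedv:
    label: RVEDV
    units: mL
    direction_of_benefit: -1
    icc: 0.98
  rvesv:
    label: RVESV
    units: mL
    direction_of_benefit: -1
    icc: 0.97
  rvsv:
    label: RVSV
    units: mL
    direction_of_benefit: 1
    icc: 0.90
anchors:
  e10:
    label: emPHasis-10
    kind: change_threshold
    threshold: 6
    improvement_sign: -1
  iswt:
    label: ISWT
    kind: change_threshold
    threshold: 47.5
    improvement_sign: 1
  survival:
    label: 1-year survival
    kind: binary_survival
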