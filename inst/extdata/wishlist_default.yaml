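prescription_dose: 30.0
slack_delta: 0.03
hard_constraints:
- structure: PTV
  type: max_dose
  bound: 33.0
- structure: patient
  type: max_dose
  bound: 33.0
objectives:
- priority: 1
  structure: PTV
  type: mean_underdose_below
  goal: 0.0
  threshold: 28.5
- priority: 2
  structure: heart
  type: mean_dose
  goal: 10.0
- priority: 3
  structure: lungs
  type: mean_dose
  goal: 13.5
- priority: 4
  structure: breast_L
  type: mean_dose
  goal: 2.0
- priority: 5
  structure: breast_R
  type: mean_dose
  goal: 2.0
- priority: 6
  structure: lungs
  type: mean_overdose_above
  goal: 1.5
  threshold: 5.0
- priority: 7
  structure: patient
  type: mean_dose
  goal: 0.0
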