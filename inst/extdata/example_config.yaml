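seed: 20180101
n_patients: 2000
study_start: 2018-01
study_end: 2023-02
sex_split: 0.445
unknown_sex_prob: 0.002
af_prob: 0.74
recording_prob:
  weight: 0.728
  creatinine: 0.943
  egfr: 0.924
  crcl: 0.735
dose_mix:
  match: 0.862
  overdose: 0.027
  underdose: 0.111
drug_mix:
  apixaban: 0.57
  rivaroxaban: 0.28
  edoxaban: 0.11
  dabigatran: 0.04
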