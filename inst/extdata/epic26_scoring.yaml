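ov_1:
  domain: overall
  values:
  - 0.0
  - 25.0
  - 50.0
  - 75.0
  - 100.0
ui_1:
  domain: urinary_incontinence
  values:
  - 100.0
  - 75.0
  - 50.0
  - 25.0
  - 0.0
ui_2:
  domain: urinary_incontinence
  values:
  - 100.0
  - 66.666666666666671
  - 33.333333333333336
  - 0.0
ui_3:
  domain: urinary_incontinence
  values:
  - 0.0
  - 25.0
  - 50.0
  - 75.0
  - 100.0
ui_4:
  domain: urinary_incontinence
  values:
  - 100.0
  - 75.0
  - 50.0
  - 25.0
  - 0.0
uo_1:
  domain: urinary_irritation
  values:
  - 100.0
  - 75.0
  - 50.0
  - 25.0
  - 0.0
uo_2:
  domain: urinary_irritation
  values:
  - 100.0
  - 75.0
  - 50.0
  - 25.0
  - 0.0
uo_3:
  domain: urinary_irritation
  values:
  - 100.0
  - 75.0
  - 50.0
  - 25.0
  - 0.0
uo_4:
  domain: urinary_irritation
  values:
  - 100.0
  - 66.666666666666671
  - 33.333333333333336
  - 0.0
bw_1:
  domain: bowel
  values:
  - 100.0
  - 75.0
  - 50.0
  - 25.0
  - 0.0
bw_2:
  domain: bowel
  values:
  - 100.0
  - 75.0
  - 50.0
  - 25.0
  - 0.0
bw_3:
  domain: bowel
  values:
  - 100.0
  - 75.0
  - 50.0
  - 25.0
  - 0.0
bw_4:
  domain: bowel
  values:
  - 100.0
  - 66.666666666666671
  - 33.333333333333336
  - 0.0
bw_5:
  domain: bowel
  values:
  - 100.0
  - 75.0
  - 50.0
  - 25.0
  - 0.0
bw_6:
  domain: bowel
  values:
  - 100.0
  - 75.0
  - 50.0
  - 25.0
  - 0.0
sx_1:
  domain: sexual
  values:
  - 0.0
  - 25.0
  - 50.0
  - 75.0
  - 100.0
sx_2:
  domain: sexual
  values:
  - 0.0
  - 25.0
  - 50.0
  - 75.0
  - 100.0
sx_3:
  domain: sexual
  values:
  - 0.0
  - 33.333333333333336
  - 66.666666666666671
  - 100.0
sx_4:
  domain: sexual
  values:
  - 0.0
  - 25.0
  - 50.0
  - 75.0
  - 100.0
sx_5:
  domain: sexual
  values:
  - 0.0
  - 25.0
  - 50.0
  - 75.0
  - 100.0
sx_6:
  domain: sexual
  values:
  - 100.0
  - 75.0
  - 50.0
  - 25.0
  - 0.0
  six_q_only: yes
hm_1:
  domain: hormonal
  values:
  - 100.0
  - 75.0
  - 50.0
  - 25.0
  - 0.0
hm_2:
  domain: hormonal
  values:
  - 100.0
  - 75.0
  - 50.0
  - 25.0
  - 0.0
hm_3:
  domain: hormonal
  values:
  - 100.0
  - 75.0
  - 50.0
  - 25.0
  - 0.0
hm_4:
  domain: hormonal
  values:
  - 100.0
  - 66.666666666666671
  - 33.333333333333336
  - 0.0
hm_5:
  domain: hormonal
  values:
  - 100.0
  - 75.0
  - 50.0
  - 25.0
  - 0.0
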