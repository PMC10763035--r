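models:
  sexual:
    domain: sexual
    intercept: 36.200000000000003
    clip_predictions: no
    terms:
      months: -0.35
      age_dx: -0.45
      race:
        ref: White
        levels:
          Asian: -3.5
          Black: 3.0
          Hispanic: -1.0
          Other: 1.0
      baseline: 0.55
      general_health:
        ref: Good
        levels:
          Excellent: 6.0
          Fair: -4.0
          Poor: -8.0
          Very good: 3.0
      psa: -0.15
      gleason:
        ref: <=6
        levels:
          '>=8': -7.0
          3+4: -2.0
          4+3: -4.0
  urinary_incontinence:
    domain: urinary_incontinence
    intercept: 65.0
    clip_predictions: no
    terms:
      months: 0.1
      age_dx: -0.5
      race:
        ref: White
        levels:
          Asian: 2.0
          Black: -2.0
          Hispanic: 1.0
          Other: 8.5
      baseline: 0.45
      general_health:
        ref: Good
        levels:
          Excellent: 4.0
          Fair: -3.0
          Poor: -6.0
          Very good: 2.0
      psa: -0.1
      gleason:
        ref: <=6
        levels:
          '>=8': -3.0
          3+4: -1.0
          4+3: -2.0
  urinary_irritation:
    domain: urinary_irritation
    intercept: 58.399999999999999
    clip_predictions: no
    terms:
      months: 0.05
      age_dx: -0.15
      race:
        ref: White
        levels:
          Asian: -1.0
          Black: 1.0
          Hispanic: -0.5
          Other: 0.5
      baseline: 0.5
      general_health:
        ref: Good
        levels:
          Excellent: 3.0
          Fair: -2.5
          Poor: -5.0
          Very good: 1.5
      psa: -0.05
      gleason:
        ref: <=6
        levels:
          '>=8': -1.5
          3+4: -0.5
          4+3: -1.0
  bowel:
    domain: bowel
    intercept: 57.100000000000001
    clip_predictions: no
    terms:
      months: 0.02
      age_dx: -0.1
      race:
        ref: White
        levels:
          Asian: 1.0
          Black: -1.0
          Hispanic: 0.5
          Other: -0.5
      baseline: 0.45
      general_health:
        ref: Good
        levels:
          Excellent: 4.0
          Fair: -3.5
          Poor: -7.0
          Very good: 2.0
      psa: -0.05
      gleason:
        ref: <=6
        levels:
          '>=8': -2.0
          3+4: -0.5
          4+3: -1.0
  hormonal:
    domain: hormonal
    intercept: 51.799999999999997
    clip_predictions: no
    terms:
      months: 0.03
      age_dx: -0.1
      race:
        ref: White
        levels:
          Asian: -1.5
          Black: 0.5
          Hispanic: -1.0
          Other: 1.0
      baseline: 0.5
      general_health:
        ref: Good
        levels:
          Excellent: 5.0
          Fair: -5.0
          Poor: -9.0
          Very good: 2.5
      psa: -0.1
      gleason:
        ref: <=6
        levels:
          '>=8': -2.5
          3+4: -1.0
          4+3: -1.5
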