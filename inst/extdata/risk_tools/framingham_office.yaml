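tool_id: framingham
mode: office
type: equation
synthetic: yes
note: Synthetic stand-in coefficients with the structure of the published office/lab
  tool families; not a transcription of any published tool.
outcomes:
  chd:
    female:
      s0: 0.982
      predictors:
      - name: age
        transform: identity
        beta: 0.0756
        mean: 55.0
        lo: 35.0
        hi: 90.0
      - name: sbp
        transform: identity
        beta: 0.0162
        mean: 125.0
        lo: 80.0
        hi: 250.0
      - name: smoker
        transform: identity
        beta: 0.486
        mean: 0.1
      - name: diabetes
        transform: identity
        beta: 0.594
        mean: 0.1
      - name: bmi
        transform: identity
        beta: 0.027
        mean: 23.0
        lo: 15.0
        hi: 45.0
    male:
      s0: 0.97
      predictors:
      - name: age
        transform: identity
        beta: 0.07776
        mean: 54.0
        lo: 35.0
        hi: 90.0
      - name: sbp
        transform: identity
        beta: 0.01728
        mean: 126.0
        lo: 80.0
        hi: 250.0
      - name: smoker
        transform: identity
        beta: 0.54
        mean: 0.3
      - name: diabetes
        transform: identity
        beta: 0.648
        mean: 0.1
      - name: bmi
        transform: identity
        beta: 0.03024
        mean: 23.0
        lo: 15.0
        hi: 45.0
  stroke:
    female:
      s0: 0.988
      predictors:
      - name: age
        transform: identity
        beta: 0.0864
        mean: 55.0
        lo: 35.0
        hi: 90.0
      - name: sbp
        transform: identity
        beta: 0.02376
        mean: 125.0
        lo: 80.0
        hi: 250.0
      - name: smoker
        transform: identity
        beta: 0.378
        mean: 0.1
      - name: diabetes
        transform: identity
        beta: 0.54
        mean: 0.1
      - name: bmi
        transform: identity
        beta: 0.0162
        mean: 23.0
        lo: 15.0
        hi: 45.0
    male:
      s0: 0.984
      predictors:
      - name: age
        transform: identity
        beta: 0.08856
        mean: 54.0
        lo: 35.0
        hi: 90.0
      - name: sbp
        transform: identity
        beta: 0.02484
        mean: 126.0
        lo: 80.0
        hi: 250.0
      - name: smoker
        transform: identity
        beta: 0.432
        mean: 0.3
      - name: diabetes
        transform: identity
        beta: 0.594
        mean: 0.1
      - name: bmi
        transform: identity
        beta: 0.01836
        mean: 23.0
        lo: 15.0
        hi: 45.0
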