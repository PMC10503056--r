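tool_id: who2019
mode: office
type: equation
synthetic: yes
note: Synthetic stand-in coefficients with the structure of the published office/lab
  tool families; not a transcription of any published tool.
outcomes:
  chd:
    female:
      s0: 0.985
      predictors:
      - name: age
        transform: identity
        beta: 0.07
        mean: 55.0
        lo: 35.0
        hi: 90.0
      - name: sbp
        transform: identity
        beta: 0.015
        mean: 125.0
        lo: 80.0
        hi: 250.0
      - name: smoker
        transform: identity
        beta: 0.45
        mean: 0.1
      - name: diabetes
        transform: identity
        beta: 0.55
        mean: 0.1
      - name: bmi
        transform: identity
        beta: 0.025
        mean: 23.0
        lo: 15.0
        hi: 45.0
    male:
      s0: 0.975
      predictors:
      - name: age
        transform: identity
        beta: 0.072
        mean: 54.0
        lo: 35.0
        hi: 90.0
      - name: sbp
        transform: identity
        beta: 0.016
        mean: 126.0
        lo: 80.0
        hi: 250.0
      - name: smoker
        transform: identity
        beta: 0.5
        mean: 0.3
      - name: diabetes
        transform: identity
        beta: 0.6
        mean: 0.1
      - name: bmi
        transform: identity
        beta: 0.028
        mean: 23.0
        lo: 15.0
        hi: 45.0
  stroke:
    female:
      s0: 0.99
      predictors:
      - name: age
        transform: identity
        beta: 0.08
        mean: 55.0
        lo: 35.0
        hi: 90.0
      - name: sbp
        transform: identity
        beta: 0.022
        mean: 125.0
        lo: 80.0
        hi: 250.0
      - name: smoker
        transform: identity
        beta: 0.35
        mean: 0.1
      - name: diabetes
        transform: identity
        beta: 0.5
        mean: 0.1
      - name: bmi
        transform: identity
        beta: 0.015
        mean: 23.0
        lo: 15.0
        hi: 45.0
    male:
      s0: 0.986
      predictors:
      - name: age
        transform: identity
        beta: 0.082
        mean: 54.0
        lo: 35.0
        hi: 90.0
      - name: sbp
        transform: identity
        beta: 0.023
        mean: 126.0
        lo: 80.0
        hi: 250.0
      - name: smoker
        transform: identity
        beta: 0.4
        mean: 0.3
      - name: diabetes
        transform: identity
        beta: 0.55
        mean: 0.1
      - name: bmi
        transform: identity
        beta: 0.017
        mean: 23.0
        lo: 15.0
        hi: 45.0
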