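tool_id: globorisk
mode: lab
type: equation
synthetic: yes
note: Synthetic stand-in coefficients with the structure of the published office/lab
  tool families; not a transcription of any published tool.
outcomes:
  chd:
    female:
      s0: 0.987
      predictors:
      - name: age
        transform: identity
        beta: 0.0644
        mean: 55.0
        lo: 35.0
        hi: 90.0
      - name: sbp
        transform: identity
        beta: 0.0138
        mean: 125.0
        lo: 80.0
        hi: 250.0
      - name: smoker
        transform: identity
        beta: 0.414
        mean: 0.1
      - name: diabetes
        transform: identity
        beta: 0.506
        mean: 0.1
      - name: total_cholesterol
        transform: identity
        beta: 0.00368
        mean: 200.0
        lo: 100.0
        hi: 400.0
    male:
      s0: 0.978
      predictors:
      - name: age
        transform: identity
        beta: 0.06624
        mean: 54.0
        lo: 35.0
        hi: 90.0
      - name: sbp
        transform: identity
        beta: 0.01472
        mean: 126.0
        lo: 80.0
        hi: 250.0
      - name: smoker
        transform: identity
        beta: 0.46
        mean: 0.3
      - name: diabetes
        transform: identity
        beta: 0.552
        mean: 0.1
      - name: total_cholesterol
        transform: identity
        beta: 0.00414
        mean: 200.0
        lo: 100.0
        hi: 400.0
  stroke:
    female:
      s0: 0.991
      predictors:
      - name: age
        transform: identity
        beta: 0.0736
        mean: 55.0
        lo: 35.0
        hi: 90.0
      - name: sbp
        transform: identity
        beta: 0.02024
        mean: 125.0
        lo: 80.0
        hi: 250.0
      - name: smoker
        transform: identity
        beta: 0.322
        mean: 0.1
      - name: diabetes
        transform: identity
        beta: 0.46
        mean: 0.1
      - name: total_cholesterol
        transform: identity
        beta: 0.00092
        mean: 200.0
        lo: 100.0
        hi: 400.0
    male:
      s0: 0.987
      predictors:
      - name: age
        transform: identity
        beta: 0.07544
        mean: 54.0
        lo: 35.0
        hi: 90.0
      - name: sbp
        transform: identity
        beta: 0.02116
        mean: 126.0
        lo: 80.0
        hi: 250.0
      - name: smoker
        transform: identity
        beta: 0.368
        mean: 0.3
      - name: diabetes
        transform: identity
        beta: 0.506
        mean: 0.1
      - name: total_cholesterol
        transform: identity
        beta: 0.001104
        mean: 200.0
        lo: 100.0
        hi: 400.0
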