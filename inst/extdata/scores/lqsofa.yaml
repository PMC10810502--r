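# LqSOFA: four unit-weight components, maximum score 4.
# Heart-rate and respiratory-rate thresholds are editable defaults
# approximating published hospital-based 99th-percentile charts for
# high-resource settings (Bonafide et al., Pediatrics 2013); replace them
# with the exact chart values in use locally before clinical application.
# Band edges are months, lower-inclusive / upper-exclusive, covering
# [2, 192).
name: LqSOFA
components:
- name: heart_rate_high
  predicate: vital-above-cutoff
  weight: 1
  variable: heart_rate
  cutoffs:
  - {lower: 2, upper: 6, threshold: 205}
  - {lower: 6, upper: 9, threshold: 201}
  - {lower: 9, upper: 12, threshold: 197}
  - {lower: 12, upper: 18, threshold: 191}
  - {lower: 18, upper: 24, threshold: 182}
  - {lower: 24, upper: 36, threshold: 173}
  - {lower: 36, upper: 48, threshold: 167}
  - {lower: 48, upper: 72, threshold: 157}
  - {lower: 72, upper: 96, threshold: 146}
  - {lower: 96, upper: 144, threshold: 138}
  - {lower: 144, upper: 192, threshold: 129}
- name: respiratory_rate_high
  predicate: vital-above-cutoff
  weight: 1
  variable: respiratory_rate
  cutoffs:
  - {lower: 2, upper: 6, threshold: 71}
  - {lower: 6, upper: 9, threshold: 66}
  - {lower: 9, upper: 12, threshold: 61}
  - {lower: 12, upper: 18, threshold: 58}
  - {lower: 18, upper: 24, threshold: 55}
  - {lower: 24, upper: 36, threshold: 52}
  - {lower: 36, upper: 48, threshold: 50}
  - {lower: 48, upper: 72, threshold: 46}
  - {lower: 72, upper: 96, threshold: 43}
  - {lower: 96, upper: 144, threshold: 41}
  - {lower: 144, upper: 192, threshold: 40}
- name: crt_prolonged
  predicate: crt-prolonged
  weight: 1
  threshold_seconds: 3
- name: bcs_low
  predicate: bcs-below
  weight: 1
  value: 5
policy:
  exclusion_threshold: 2
  single_missing: normal
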