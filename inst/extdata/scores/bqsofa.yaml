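# BqSOFA: respiratory rate above cohort-derived 90th-percentile cutoffs in
# three memorable age bands, CRT > 3 s, Blantyre Coma Score < 5, and
# moderate/severe pallor. Four unit-weight components, maximum score 4.
# The respiratory-rate thresholds are editable defaults in the spirit of
# "easy to remember at the bedside"; re-derive them from a local cohort
# with derive_percentile_cutoffs() where data allow.
name: BqSOFA
components:
- name: respiratory_rate_high
  predicate: vital-above-cutoff
  weight: 1
  variable: respiratory_rate
  cutoffs:
  - {lower: 2, upper: 12, threshold: 60}
  - {lower: 12, upper: 60, threshold: 50}
  - {lower: 60, upper: 192, threshold: 40}
- name: crt_prolonged
  predicate: crt-prolonged
  weight: 1
  threshold_seconds: 3
- name: bcs_low
  predicate: bcs-below
  weight: 1
  value: 5
- name: pallor
  predicate: flag-present
  weight: 1
  field: pallor
policy:
  exclusion_threshold: 2
  single_missing: normal
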