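# FEAST-PET configuration TEMPLATE -- not a transcription of the published
# score. The Paediatric Emergency Triage score is described with eight
# clinical parameters in some sources and eleven components in others; the
# engine supports either via integer weights, and published cutoff tables
# for it run above 4, implying a maximum score greater than 4. Fill in the
# authoritative component list, weights and thresholds before use; the
# slots below only illustrate the expected shape. Components referencing
# fields outside the canonical record (temperature_gradient,
# deep_breathing, lung_crepitations, weak_radial_pulse, prostration) need
# matching yes/no passthrough columns in the cohort CSV.
name: FEAST-PET (template)
components:
- name: temperature_gradient
  predicate: flag-present
  weight: 1
  field: temperature_gradient
- name: deep_breathing
  predicate: flag-present
  weight: 1
  field: deep_breathing
- name: lung_crepitations
  predicate: flag-present
  weight: 1
  field: lung_crepitations
- name: weak_radial_pulse
  predicate: flag-present
  weight: 2
  field: weak_radial_pulse
- name: crt_prolonged
  predicate: crt-prolonged
  weight: 1
  threshold_seconds: 3
- name: pallor
  predicate: flag-present
  weight: 1
  field: pallor
- name: prostration
  predicate: flag-present
  weight: 1
  field: prostration
- name: bcs_low
  predicate: bcs-below
  weight: 2
  value: 5
policy:
  exclusion_threshold: 2
  single_missing: normal
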