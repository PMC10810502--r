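# Development-cohort-style 90th-percentile respiratory-rate cutoffs in
# three memorable age bands (months, half-open). Editable defaults; must
# stay identical to the respiratory-rate table inside scores/bqsofa.yaml.
variable: respiratory_rate
bands:
- {lower: 2, upper: 12, threshold: 60}
- {lower: 12, upper: 60, threshold: 50}
- {lower: 60, upper: 192, threshold: 40}
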