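# Development-cohort-style 90th-percentile heart-rate cutoffs in three
# age bands (months, half-open). Editable defaults; used by the recorded
# development sequence before heart rate is dropped from the score.
variable: heart_rate
bands:
- {lower: 2, upper: 12, threshold: 180}
- {lower: 12, upper: 60, threshold: 160}
- {lower: 60, upper: 192, threshold: 140}
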