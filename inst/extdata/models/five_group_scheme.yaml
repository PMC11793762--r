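labels:
- very_low
- low
- moderate
- high
- very_high
cutoffs:
- 0.006
- 0.031
- 0.188
- 0.456
closed:
- right
- left
- right
- left
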