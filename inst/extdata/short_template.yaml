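name: short_template
barcode_length: 30
random_positions:
- 1
- 2
- 3
- 4
- 6
- 7
- 8
- 9
- 11
- 12
- 13
- 14
- 15
- 17
- 18
- 19
- 20
- 22
- 23
- 25
- 26
- 27
- 29
- 30
fixed_positions:
  '5': C
  '10': A
  '16': G
  '21': T
  '24': A
  '28': C
target_region:
- 31
- 38
length_window:
- 34.0
- 39.0

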