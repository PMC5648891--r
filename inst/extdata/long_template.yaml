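name: long_template
barcode_length: 50
random_positions:
- 1
- 2
- 3
- 5
- 6
- 7
- 9
- 10
- 11
- 13
- 14
- 15
- 17
- 18
- 19
- 21
- 22
- 23
- 25
- 26
- 27
- 29
- 30
- 31
- 33
- 34
- 35
- 37
- 38
- 39
- 41
- 42
- 43
- 44
- 46
- 47
- 48
- 49
fixed_positions:
  '4': A
  '8': C
  '12': G
  '16': T
  '20': A
  '24': C
  '28': G
  '32': T
  '36': A
  '40': C
  '45': G
  '50': T
target_region:
- 51
- 100
length_window:
- 90.0
- .na.real

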