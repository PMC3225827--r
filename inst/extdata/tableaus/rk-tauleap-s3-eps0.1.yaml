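s: 3
eps: 0.10000000000000001
r:
- 1.0
- 0.33280426541637637
- 0.04240169028535682
l: 3.94571911204945014
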