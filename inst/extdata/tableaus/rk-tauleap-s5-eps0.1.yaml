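s: 5
eps: 0.10000000000000001
r:
- 1.0
- 0.35233453499482348
- 0.06608591755567114
- 0.00587285320776631
- 0.0001951336758967
l: 10.71683395921533943
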