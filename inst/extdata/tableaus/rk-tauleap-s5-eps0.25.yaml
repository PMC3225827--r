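s: 5
eps: 0.25
r:
- 1.0
- 0.29539849797678386
- 0.04157059931623953
- 0.00265583153459605
- 6.23569582709928547e-05
l: 15.42635133522697366
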