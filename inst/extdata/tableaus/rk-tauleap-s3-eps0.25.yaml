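s: 3
eps: 0.25
r:
- 1.0
- 0.27537335431156074
- 0.02561383229852721
l: 5.89602203369140732
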