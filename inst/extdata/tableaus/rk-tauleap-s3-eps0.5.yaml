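s: 3
eps: 0.5
r:
- 1.0
- 0.23447484511638569
- 0.0169177732911854
l: 8.12060864766438861
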