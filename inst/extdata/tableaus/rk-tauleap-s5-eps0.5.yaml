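s: 5
eps: 0.5
r:
- 1.0
- 0.25315426481051578
- 0.02798809795010343
- 0.00136038359019405
- 2.39735648179010907e-05
l: 20.93653845278421954
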