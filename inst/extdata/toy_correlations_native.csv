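Article_ID,ES,N1,N2
art-001,0.12,120,120
art-002,0.45,36,36
art-003,-0.3,55,55
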