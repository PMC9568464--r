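# Canonical column -> header used in the source file
study_id: Article_ID
r: ES
n1: N1
n2: N2
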