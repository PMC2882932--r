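T1	true
T2	true
T3	false
T4	false
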