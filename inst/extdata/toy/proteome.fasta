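>T1 toy protein
MVAPTKLLGDEF
>T2 toy protein
GGCPSKDDEEFF
>T3 toy protein
DDEEFFGGHHII
>T4 toy protein
LLMMNNQQRRVV
>T5 toy protein
WWAPSKYYVVMM
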