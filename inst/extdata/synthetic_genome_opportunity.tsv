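Context	Frequency
ACA	0.03125
ACC	0.03125
ACG	0.03125
ACT	0.03125
CCA	0.03125
CCC	0.03125
CCG	0.03125
CCT	0.03125
GCA	0.03125
GCC	0.03125
GCG	0.03125
GCT	0.03125
TCA	0.03125
TCC	0.03125
TCG	0.03125
TCT	0.03125
ATA	0.03125
ATC	0.03125
ATG	0.03125
ATT	0.03125
CTA	0.03125
CTC	0.03125
CTG	0.03125
CTT	0.03125
GTA	0.03125
GTC	0.03125
GTG	0.03125
GTT	0.03125
TTA	0.03125
TTC	0.03125
TTG	0.03125
TTT	0.03125
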