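Context	Frequency
ACA	0.0342105263157895
ACC	0.0342105263157895
ACG	0.0105263157894737
ACT	0.0342105263157895
CCA	0.0342105263157895
CCC	0.0342105263157895
CCG	0.0105263157894737
CCT	0.0342105263157895
GCA	0.0342105263157895
GCC	0.0342105263157895
GCG	0.0105263157894737
GCT	0.0342105263157895
TCA	0.0342105263157895
TCC	0.0342105263157895
TCG	0.0105263157894737
TCT	0.0342105263157895
ATA	0.0342105263157895
ATC	0.0342105263157895
ATG	0.0342105263157895
ATT	0.0342105263157895
CTA	0.0342105263157895
CTC	0.0342105263157895
CTG	0.0342105263157895
CTT	0.0342105263157895
GTA	0.0342105263157895
GTC	0.0342105263157895
GTG	0.0342105263157895
GTT	0.0342105263157895
TTA	0.0342105263157895
TTC	0.0342105263157895
TTG	0.0342105263157895
TTT	0.0342105263157895
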