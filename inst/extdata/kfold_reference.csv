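fold,accuracy_pct,f1
1,92.5,0.96
2,93.4,0.97
3,93.5,0.97
4,93.2,0.96
5,92.6,0.96
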