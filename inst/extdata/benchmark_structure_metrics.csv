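structure,ap_pct,ppv_pct,s_pct,f1,specificity_pct
4CH,99.5,99.5,100,0.9975,99.2
LV,99.5,99.2,100,0.9959,98.4
LA,97.9,95.0,92.0,0.9348,98.4
AO,90.3,90.0,87.0,0.8847,93.7
RV,89.4,92.2,84.1,0.8796,96.5
AA,94.2,93.7,89.2,0.9139,97.4
SVC,95.1,99.2,88.7,0.9366,97.9
PA,94.8,93.9,96.4,0.9513,99.6
MPA,95.7,92.5,96.8,0.9460,97.2
T,86.9,90.9,75.5,0.8249,97.2
All,94.3,94.6,91.0,0.9277,NA
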