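gene,beta
ALDH3A2,0.452
CISD2,0.418
AKR1C3,-0.382
MT1G,-0.214
NOX4,0.161
TXNRD1,0.263
PTGS2,-0.147
NFE2L2,0.198
FTH1,0.126
GPX4,0.173
SLC7A11,0.221
ACSL4,-0.205
AKR1C2,-0.118
ZEB1,-0.092
GDF15,0.135
CBS,0.084
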