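trait,h2
BWT,0.10
WWT,0.19
LW6,0.30
EMD,0.35
EMDad,0.43
EMW,0.24
EMWad,0.31
FDM,0.28
FDMad,0.33
PRESLT,0.25
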