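trait,h2,r_gb0,enp_printed
WWT,0.19,0.19,1
EMD,0.35,0.40,2
CCWT,0.23,0.44,4
HCWT,0.21,0.46,5
SFXWT,0.19,0.47,6
CGRM,0.23,0.54,7
SFLEG,0.18,0.52,8
DRESS,0.24,0.67,13
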