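region,rc_dates,rc_sites,tr_dates,tr_sites
UUSW,1531,482,15077,770
CMV,361,84,4352,219
NRG,83,40,2306,146
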