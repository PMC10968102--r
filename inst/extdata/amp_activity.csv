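peptide_id,mhc,censored
melittin,0.2,0
arenicin-2,4,0
arenicin-1_V8R,125,0
ChDode,40,0
PcDode,>128,1
capitellacin,>128,1
tachyplesin-1,25,0
protegrin-1,4,0
thanatin,500,0
polyphemusin-1,25,0
arenicin-3,130,0
gomesin,150,0
PV5,50,0
fowlicidin-1,2,0
magainin-2,300,0
MSI-594,300,0
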