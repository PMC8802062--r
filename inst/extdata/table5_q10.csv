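transition,rh_pct,q10,q10_sd
20-30,30,1.65,0.37
20-30,50,2.57,0.39
20-30,75,2.92,0.64
20-30,80,4.61,2.39
30-40,30,2.52,0.16
30-40,50,1.74,0.37
30-40,75,3.56,0.59
30-40,80,3.45,0.52
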