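temp_c,rh_pct,terminal_day
20,30,450
20,50,380
20,75,225
20,80,40
30,30,380
30,50,230
30,75,150
30,80,25
40,30,300
40,50,150
40,75,100
40,80,15
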