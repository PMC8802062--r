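grade_number,name,munsell_hue,munsell_value,munsell_chroma,r,g,b,L_lab,a,b_lab,L_lch,C,h
1,Light cream,2.5Y,8,4,223,200,150,81,1,28,81,28,88
2,Cream,10YR,7,4,202,171,128,72,5,27,72,27,79
3,Golden,7.5YR,6,4,179,142,110,62,9,22,62,24,67
4,Light brown,5YR,5,4,154,115,89,52,12,21,52,24,60
5,Reddish brown,2.5YR,4,4,130,87,69,41,16,18,41,24,49
6,Dark reddish brown,10R,3,4,105,61,52,31,18,14,31,23,37
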