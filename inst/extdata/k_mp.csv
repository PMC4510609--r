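wavelength_nm,k
400,0.32
410,0.44
420,0.60
430,0.74
440,0.85
450,0.94
460,1.00
470,0.96
480,0.85
490,0.63
500,0.36
510,0.17
520,0.07
530,0.025
540,0.008
550,0.002
560,0
800,0
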