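wavelength_nm,k
400,0.36
410,0.38
420,0.42
430,0.47
440,0.55
450,0.64
460,0.73
470,0.83
480,0.92
490,0.97
500,1.00
510,0.97
520,0.88
530,0.73
540,0.55
550,0.38
560,0.23
570,0.12
580,0.05
590,0
800,0
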