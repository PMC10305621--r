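strain_id,E,F,G,H
t01,1,0,0,0
t02,1,1,0,0
t03,1,1,0,0
t04,1,0,1,0
t05,1,0,0,1
t06,0,1,1,0
t07,0,1,0,1
t08,0,1,0,0
t09,0,0,1,1
t10,0,0,1,1
t11,0,0,1,0
t12,0,0,0,1
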