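strain_id,A,B,C,D
s01,0,0,0,1
s02,1,0,0,1
s03,1,0,0,1
s04,0,1,0,0
s05,1,1,0,0
s06,1,0,1,0
s07,1,1,0,0
s08,0,1,1,0
s09,0,1,0,0
s10,0,0,1,1
s11,0,0,1,1
s12,0,0,1,0
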