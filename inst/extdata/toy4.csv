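id,age_day,stage,eggs
A,0,1,0
A,1,1,0
A,2,2,0
A,3,2,0
A,4,2,0
A,5,3,0
A,6,3,0
A,7,4,10
A,8,4,20
A,9,4,10
B,0,1,0
C,0,1,0
C,1,1,0
C,2,2,0
C,3,2,0
C,4,2,0
D,0,1,0
D,1,1,0
D,2,2,0
D,3,2,0
D,4,2,0
D,5,3,0
D,6,3,0
D,7,5,0
D,8,5,0
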