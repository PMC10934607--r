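label,subject,tp,fp,fn
S1,1,378,0,0
S1,2,188,2,3
S1,3,158,13,8
S1,4,185,20,19
S1,5,336,0,0
S1,6,154,0,0
S2,1,378,0,0
S2,2,160,44,31
S2,3,160,10,6
S2,4,196,13,8
S2,5,336,0,0
S2,6,151,3,3
S1S2,1,377,1,1
S1S2,2,163,28,28
S1S2,3,95,37,71
S1S2,4,152,52,52
S1S2,5,303,2,33
S1S2,6,154,0,0
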