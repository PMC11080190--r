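class,count
U1,55
U2,52
U3,50
U4,50
U5,54
U6,63
U7,49
U8,51
L1,53
L2,53
L3,54
L4,52
L5,57
L6,54
L7,45
L8,58
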