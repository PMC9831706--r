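class,0,1,2,3,4
0,20,0,14,0,0
1,2,3,0,0,0
2,3,0,29,0,0
3,0,0,9,10,0
4,1,0,2,0,10
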