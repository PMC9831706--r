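class,0,1,2,3,4,5
0,1847,5,28,0,0,0
1,65,79,42,0,1,2
2,576,34,639,14,28,53
3,6,1,17,38,8,1
4,9,0,87,2,152,25
5,3,0,6,0,12,325
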