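alpha,rank,count
1,1,25
1,2,13
1,3,9
1,4,7
1,5,5
1,6,5
1,7,4
1,8,4
1,9,3
1,10,3
1,11,3
1,12,3
1,13,2
1,14,2
1,15,2
1,16,2
1,17,2
1,18,2
1,19,2
1,20,2
1,21,2
1,22,2
1,23,2
1,24,2
2,1,92
2,2,23
2,3,11
2,4,6
2,5,4
2,6,3
2,7,2
2,8,2
2,9,2
4,1,139
4,2,9
4,3,2
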