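q01,q02,q03,q04,q05,q06,q07,q08,q09,q10,q11,q12,q13,q14,q15,q16
3,6,6,5,4,6,5,3,2,4,3,5,5,5,4,5
7,7,6,7,7,6,5,6,7,7,7,7,4,2,6,6
7,6,3,4,4,5,1,4,1,5,1,2,4,5,5,5
7,6,5,7,7,7,7,7,7,7,7,7,7,7,7,7
3,7,4,7,7,5,7,6,7,6,5,7,7,7,6,5
4,5,3,2,2,3,7,5,5,1,1,4,2,3,1,3
7,7,7,7,7,7,4,7,6,7,7,7,5,7,6,7
4,5,5,5,5,2,1,3,3,5,6,4,2,3,4,3
2,3,4,1,4,3,1,1,5,3,1,4,3,7,7,3
6,7,5,5,3,7,7,5,7,6,7,7,7,1,6,6
7,7,6,7,6,6,7,7,6,6,7,7,7,5,6,6
6,4,7,5,5,6,5,4,7,6,6,5,5,7,6,5
6,6,3,6,5,5,4,7,4,3,3,4,4,7,5,4
6,5,5,3,6,4,7,6,1,7,5,5,6,6,5,3
6,6,4,5,7,7,7,6,6,6,5,5,6,5,7,7
6,7,7,7,5,6,4,7,4,7,5,6,6,5,5,3
5,7,7,7,5,5,6,4,7,7,4,7,7,6,5,4
2,3,4,5,1,5,6,7,3,4,3,5,4,7,5,1
6,7,7,6,7,6,5,4,7,4,5,7,5,4,7,6
7,6,6,7,7,6,7,7,6,7,4,5,7,6,6,4
7,7,7,7,6,7,7,7,7,7,5,7,7,7,5,7
7,6,7,7,6,5,7,5,7,5,5,7,4,4,7,7
4,5,5,6,7,6,2,5,5,7,2,3,2,5,4,4
5,6,2,4,6,6,7,5,1,4,1,4,4,4,6,1
5,6,7,6,5,2,3,7,4,5,5,4,7,4,6,4
6,5,7,4,6,4,5,3,4,7,6,4,3,2,7,7
3,1,3,1,2,1,1,1,1,2,1,1,6,3,2,2
7,7,7,7,7,7,7,7,7,7,7,7,7,7,7,7
5,7,5,6,5,7,4,5,6,4,4,5,6,5,5,7
4,3,7,5,6,5,6,4,6,6,5,3,5,7,4,6
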