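annex_code,rl_code,relation,include
3110,C1.1a,same,1
3120,C1.1b,narrower,1
3120,C1.6b,narrower,1
3130,C1.1a,overlap,1
3130,C1.6a,low_importance,1
3140,C1.2a,same,1
3150,C1.2b,close,1
3160,C1.4,same,1
3170,C1.5,close,1
3170,C1.6b,low_importance,1
3180,C1.6a,wider,1
3190,C1.6a,wider,1
31A0,C1.5,narrower,1
3210,C2.2,same,1
3220,C2.2,close,1
3220,C2.3,low_importance,1
3230,C2.2,narrower,1
3240,C2.1,overlap,1
3250,C2.5,close,1
3260,C2.3,same,1
3270,C2.4,close,1
3280,C2.5,close,1
3290,C2.5,same,1
32A0,C2.6,narrower,1
7110,D1.1,same,1
7120,D1.1,wider,1
7130,D1.2,same,1
7140,D2.2,same,1
7150,D2.2,narrower,1
7160,D2.3,close,1
7210,D4.1,narrower,1
7220,D4.1,narrower,1
7230,D4.1,same,1
7240,D4.2,narrower,1
7310,D3.1,same,1
7320,D3.2,same,1
9080,T1.1,narrower,1
91D0,T1.2,close,1
91E0,T1.1,same,1
91F0,T1.3,same,1
92A0,T1.4,wider,1
92A0,T1.3,low_importance,1
92B0,F9.3,narrower,1
92C0,T1.4,close,1
92D0,F9.3,close,1
1130,X02,wider,1
1650,X03,same,1
2190,B1.8,close,1
4010,F4.1,same,1
4020,F4.1,narrower,1
6410,E3.1,same,1
6430,E3.2,same,1
6440,E3.5,close,1
6450,E3.3,same,1
6460,E3.4,narrower,1
6540,E3.5,narrower,1
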