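rl_code,regions
C1.1a,Alpine;Boreal;Continental
C1.1b,Atlantic;Boreal
C1.2a,Alpine;Atlantic;Boreal;Continental
C1.2b,UNSPECIFIED
C1.3,UNSPECIFIED
C1.4,Alpine;Atlantic;Boreal;Continental
C1.5,Continental;Mediterranean;Pannonian
C1.6a,UNSPECIFIED
C1.6b,Mediterranean
C2.1,Alpine;Atlantic;Boreal;Continental
C2.2,Alpine;Boreal
C2.3,UNSPECIFIED
C2.4,Atlantic;Continental;Mediterranean
C2.5,Mediterranean;Pannonian
C2.6,Mediterranean
D1.1,Alpine;Atlantic;Boreal;Continental
D1.2,Atlantic;Boreal
D2.1,Boreal
D2.2,Alpine;Atlantic;Boreal;Continental
D2.3,UNSPECIFIED
D3.1,Boreal;Continental
D3.2,Boreal
D4.1,UNSPECIFIED
D4.2,Alpine;Boreal
T1.1,Alpine;Atlantic;Boreal;Continental;Pannonian
T1.2,UNSPECIFIED
T1.3,Atlantic;Continental;Mediterranean;Pannonian
T1.4,Mediterranean
F9.1,Alpine;Continental;Mediterranean
F9.2,UNSPECIFIED
F9.3,Mediterranean
F4.1,Atlantic;Boreal;Continental
E3.1,Atlantic;Continental
E3.2,UNSPECIFIED
E3.3,Boreal
E3.4,Mediterranean
E3.5,Continental;Pannonian
B1.8,Atlantic;Boreal;Continental
X02,UNSPECIFIED
X03,Boreal;Continental
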