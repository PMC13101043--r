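annex_code,regions
1130,Alpine;Atlantic;Boreal;Continental;Mediterranean;Pannonian
1650,Boreal;Continental
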