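alias,region
Alpine,Alpine
Atlantic,Atlantic
Black Sea,BlackSea
BlackSea,BlackSea
Boreal,Boreal
Continental,Continental
Macaronesian,Macaronesian
Mediterranean,Mediterranean
Pannonian,Pannonian
Steppic,Steppic
Marine Atlantic,MarineAtlantic
MarineAtlantic,MarineAtlantic
Marine Baltic,MarineBaltic
MarineBaltic,MarineBaltic
Marine Black Sea,MarineBlackSea
MarineBlackSea,MarineBlackSea
Marine Macaronesian,MarineMacaronesian
MarineMacaronesian,MarineMacaronesian
Marine Mediterranean,MarineMediterranean
MarineMediterranean,MarineMediterranean
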