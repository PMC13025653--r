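sequence,mass,alc,rt,area,ranker,toxin,solubility
LMFP,928,NA,17.3264,640000,0.967304,Non-Toxin,good
FEGLFR,767.87,NA,13.9416,138000,0.8536,Non-Toxin,good
QLPSYR,762.85,NA,9.3308,5540000,0.525549,Non-Toxin,good
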