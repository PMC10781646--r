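Mcm2
Mcm4
Mcm5
Mcm6
Pcna
Gins2
Uhrf1
Rrm1
Rrm2
Tyms
Fen1
Slbp
Ccne2
Cdc6
Cdc45
Hells
Top2a
Mki67
Cenpa
Cenpe
Cenpf
Bub1
Bub1b
Ccnb1
Ccnb2
Cdk1
Aurka
Aurkb
Plk1
Tpx2
Ube2c
Birc5
Hmgb2
Nusap1
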