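Isg15
Ifit1
Ifit2
Ifit3
Irf7
Irf9
Oasl1
Oasl2
Oas1a
Oas2
Oas3
Mx1
Mx2
Rsad2
Usp18
Stat1
Stat2
Bst2
Cmpk2
Ifi27
Ifi44
Ifih1
Ddx58
Ddx60
Zbp1
Xaf1
Gbp2
Gbp3
Slfn5
Rtp4
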