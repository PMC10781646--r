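Fos
Fosb
Jun
Junb
Jund
Egr1
Atf3
Hspa1a
Hspa1b
Hspa8
Hspb1
Hsph1
Dnajb1
Ier2
Ier3
Zfp36
Socs3
Klf2
Klf4
Klf6
Dusp1
Btg2
Cyr61
Nr4a1
Ubc
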