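# Default marker panels for cluster annotation.
EC: [PECAM1, KDR, CDH5]
VEC: [CD34, PLVAP]
LEC: [CCL21, PROX1, LYVE1]
proliferation: [AURKB, MKI67, INCENP, BIRC5, CDCA8]
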