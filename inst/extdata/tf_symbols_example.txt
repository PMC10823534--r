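# Example transcription-factor symbol list for marker calling in
# mode = "tf" (cell-cycle-associated TFs; supply a full TF database
# export, e.g. TRRUST v2 symbols, for real analyses).
E2F1
E2F3
E2F7
E2F8
FOXM1
MYBL1
MYBL2
MXD3
PBX3
PBX4
DNMT1
ARNTL2
LEF1
EBF4
TFDP1
LIN54
ETV4
PRDM5
MBD3
MAZ
MAFG
TERF1
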