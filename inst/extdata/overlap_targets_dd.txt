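ALB
APP
AR
CACNA1C
CAMK2A
CRH
DLG3
FKBP4
GAD2
MAOA
MAOB
NCAM1
NOS2
NR3C2
RAC1
SOD2
TTR
VEGFA
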