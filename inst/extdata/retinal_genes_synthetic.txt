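# Synthetic stand-in for a curated retinal-disease gene list
# (one symbol per line; the real curated databases hold 240+ genes).
IQCB1
CDH23
DTHD1
CHD3
CNGB1
RBP3
USH1C
CRX
CEP290
AIPL1
RPE65
RASGRF1
CCDC114
NPHP4
RPGR
PDE6B
RHO
PDE6A
CNGA1
LRAT
RDH12
GUCY2D
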