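# Demonstration virtual panel: severe autosomal recessive (and two
# X-linked) childhood-disorder genes that the screening pipeline can act
# on, plus large, variation-tolerant genes that serve as decoys in the
# bundled cohort. This is a small stand-in for a production panel of
# several hundred genes; panel membership is configuration, not code.
CTSD	AR
FTCD	AR
COQ2	AR
ACADVL	AR
UNC13D	AR
BRAT1	AR
AGA	AR
ALDOB	AR
ASPA	AR
CLN3	AR
CLN5	AR
CLN6	AR
CLN8	AR
GAA	AR
GALC	AR
GBA1	AR
HEXA	AR
HEXB	AR
IDUA	AR
NPC1	AR
NPC2	AR
PPT1	AR
SMPD1	AR
TPP1	AR
MECP2	XL
L1CAM	XL
TTN
OBSCN
MUC16
PLEC
AHNAK
SYNE1
FLG
DNAH5
USH2A
LAMA5
RYR3
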