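family	accession
Zn2Cys6	PF00172
Zn2Cys6	IPR001138
C2H2_ZF	PF00096
C2H2_ZF	IPR013087
RRM	PF00076
RRM	IPR000504
bZIP	PF00170
bZIP	PF07716
bZIP	IPR004827
bHLH	PF00010
bHLH	IPR011598
GATA_ZF	PF00320
GATA_ZF	IPR000679
Homeodomain	PF00046
Homeodomain	IPR001356
Myb_SANT	PF00249
Myb_SANT	IPR001005
Forkhead	PF00250
Forkhead	IPR001766
HSF	PF00447
HSF	IPR000232
HMG_Sox	PF00505
HMG_Sox	IPR009071
APSES	PF02292
APSES	IPR003163
Copper_fist	PF00649
Copper_fist	IPR001083
CBF_NFYB	PF00808
CBF_NFYB	IPR003958
NFYA	PF02045
NFYA	IPR001289
MADS_box	PF00319
MADS_box	IPR002100
AT_hook	PF02178
AT_hook	IPR017956
CCCH_ZF	PF00642
CCCH_ZF	IPR000571
BED_ZF	PF02892
BED_ZF	IPR003656
STE	PF02200
STE	IPR003120
NFX	PF01422
NFX	IPR000967
TEA	PF01285
TEA	IPR000818
Velvet	PF11754
Velvet	IPR021740
E2F	PF02319
E2F	IPR003316
NDT80_PhoG	PF05224
NDT80_PhoG	IPR007887
TBP	PF00352
TBP	IPR000814
ARID	PF01388
ARID	IPR001606
GCR1	PF12550
CP2	PF04516
CP2	IPR007604
SAND	PF01342
SAND	IPR000770
CSD	PF00313
CSD	IPR002059
MATalpha1	PF04769
MATalpha1	IPR006856
KilA_N	PF04383
KilA_N	IPR018004
RFX	PF02257
RFX	IPR003150
HTH_psq	PF05225
HTH_psq	IPR007889
Gti1_Pac2	PF09729
Gti1_Pac2	IPR018608
CENPB	PF04218
CENPB	IPR007321
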