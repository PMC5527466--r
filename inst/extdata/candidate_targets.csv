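gene_symbol,entrez_id,avg_robust_z,fold_induction,n_sirnas
CWC22,57703,5.51,14.3,4
IL17A,3605,4.63,6.2,2
ADAM29,11086,4.48,10.8,2
XAB2,56949,4.37,8.6,4
SF3B6,51639,4.35,9.4,2
TSHZ3,57616,4.08,9.2,3
SF3A3,10946,4.00,8.6,3
SF3B1,23451,3.99,11.7,4
APBA3,9546,3.96,7.8,2
RYR2,6262,3.96,10.0,2
DVL2,1856,3.92,5.5,2
LILRA1,11024,3.90,6.4,2
SNRPD3,6634,3.85,8.7,3
NOP56,10528,3.78,4.0,3
OR7A5,26659,3.75,5.4,2
SAP18,10284,3.75,6.8,4
ZNF592,9640,3.66,6.6,3
COX16,51241,3.65,7.4,2
C1orf158,93190,3.63,6.0,2
SPA17,53340,3.63,5.2,2
ZNF226,7769,3.63,6.6,2
FLNB,2317,3.57,5.7,2
PLVAP,83483,3.56,5.3,2
CCDC116,164592,3.48,4.4,2
FLYWCH2,114984,3.42,4.4,2
GRHL3,57822,3.37,4.7,2
SOS1,6654,3.35,6.4,2
PSMA2,5683,3.31,4.0,2
FAM27L,284123,3.24,5.3,2
WDR3,10885,3.23,4.5,4
HNRNPL,3191,3.21,4.9,2
PUS7,54517,3.21,2.7,3
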