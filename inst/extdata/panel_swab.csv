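locus,organism,repeat_motif,repeat_unit_len,size_min,size_max,multiplex,dye,sex_marker
PentaD,human,[AAAGA]n,5,376,449,1,JOE,FALSE
D3S1358,human,[AGAT]n[TCTA]n,4,115,147,1,6-FAM,FALSE
FGA,human,[TTTC]n,4,322,444,1,TAMRA,FALSE
D18S51,human,[GAAA]n,4,290,366,1,6-FAM,FALSE
PentaE,human,[AAAGA]n,5,379,474,1,6-FAM,FALSE
D16S539,human,[GATA]n,4,264,304,1,JOE,FALSE
D5S818,human,[AGAT]n,4,119,155,1,ATTO565,FALSE
CSF1PO,human,[AGAT]n,4,321,357,1,ATTO565,FALSE
D21S11,human,[TCTA]n[TCTG]n,4,203,259,1,6-FAM,FALSE
D13S317,human,[GATA]n,4,176,208,1,JOE,FALSE
D7S820,human,[GATA]n,4,215,247,1,JOE,FALSE
Amelogenin,human,-,6,106,112,1,TAMRA,TRUE
vWA,human,[AGAT]n,4,123,171,1,TAMRA,FALSE
D8S1179,human,[TATC]n,4,203,247,1,TAMRA,FALSE
TH01,human,[AATG]n,4,156,195,1,ATTO565,FALSE
TPOX,human,[AATG]n,4,262,290,1,ATTO565,FALSE
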