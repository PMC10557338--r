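locus,organism,repeat_motif,repeat_unit_len,size_min,size_max,multiplex,dye,sex_marker
Alb-tri-3,mosquito,[AGA]n,3,123,153,1,6-FAM,FALSE
Aealbmic11,mosquito,[TGT]n,3,188,230,1,6-FAM,FALSE
Aealbmic4,mosquito,[CAA]n,3,167,183,1,6-FAM,FALSE
Aealbmic13,mosquito,[GAT]GAC[GAT]n,3,132,171,1,HEX,FALSE
Alb-tri-18,mosquito,[ACA]n,3,250,280,1,HEX,FALSE
PentaD,human,[AAAGA]n,5,376,449,1,JOE,FALSE
D3S1358,human,[AGAT]n[TCTA]n,4,115,147,1,TAMRA,FALSE
Aealbmic12,mosquito,[GAT]n,3,155,182,1,ATTO550,FALSE
Aealbmic3,mosquito,[AAC]n,3,200,239,1,ATTO550,FALSE
FGA,human,[TTTC]n,4,322,444,1,ATTO565,FALSE
Alb-tri-21,mosquito,[AGGG]n,4,137,206,1,ATTO565,FALSE
Aealbmic7,mosquito,[TTG]nATG[TTG]n,3,194,215,1,ATTO565,FALSE
Aealbmic5,mosquito,[TGT]n,3,136,214,2,6-FAM,FALSE
D18S51,human,[GAAA]n,4,290,366,2,6-FAM,FALSE
PentaE,human,[AAAGA]n,5,379,474,2,6-FAM,FALSE
Alb-tri-46,mosquito,[TTC]n,3,158,192,2,HEX,FALSE
D16S539,human,[GATA]n,4,264,304,2,JOE,FALSE
Aealbmic9,mosquito,[GAT]n,3,128,143,2,ATTO550,FALSE
Alb-tri-20,mosquito,[GTG]n,3,165,201,2,ATTO550,FALSE
Alb-tri-25,mosquito,[CCAA]n,4,257,278,2,ATTO550,FALSE
D5S818,human,[AGAT]n,4,119,155,2,ATTO565,FALSE
Alb-tri-44,mosquito,[CAC]n,3,173,212,2,ATTO565,FALSE
CSF1PO,human,[AGAT]n,4,321,357,2,ATTO565,FALSE
Alb-tri-45,mosquito,[TTT]n,3,120,150,3,6-FAM,FALSE
Alb-tri-6,mosquito,[AGC]n,3,164,219,3,6-FAM,FALSE
D21S11,human,[TCTA]n[TCTG]n,4,203,259,3,6-FAM,FALSE
Alb-tri-33,mosquito,[GGC]n,3,137,182,3,HEX,FALSE
D13S317,human,[GATA]n,4,176,208,3,JOE,FALSE
D7S820,human,[GATA]n,4,215,247,3,JOE,FALSE
Amelogenin,human,-,6,106,112,3,TAMRA,TRUE
vWA,human,[AGAT]n,4,123,171,3,TAMRA,FALSE
D8S1179,human,[TATC]n,4,203,247,3,TAMRA,FALSE
Alb-tri-41,mosquito,[GAT]n,3,134,155,3,ATTO565,FALSE
TH01,human,[AATG]n,4,156,195,3,ATTO565,FALSE
TPOX,human,[AATG]n,4,262,290,3,ATTO565,FALSE
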