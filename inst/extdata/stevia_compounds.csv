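name,formula,mw,rings_c19,rings_c13,r1_ref,r2_ref,has_linked_carbonyl,note
Dulcoside A,C38H60O17,788.87,1,2,1.35,1.1625,FALSE,
Stevioside,C38H60O18,804.87,1,2,1.40,1.20,FALSE,source table prints the name Steviolbioside for this row; the chemistry (glucopyranosyl ester C38H60O18 with 1 C19 ring) identifies it as Stevioside
Steviolbioside,C32H50O13,642.73,0,2,0.96,0.87,TRUE,shows two C=O bands at 1706 and 1738 cm-1 (modified C17 site)
Rubusoside,C32H50O13,642.73,1,1,1.04,0.93,FALSE,
Rebaudioside A,C44H70O23,967.01,1,3,1.74,1.455,FALSE,
Rebaudioside B,C38H60O18,804.87,0,3,1.45,1.2375,FALSE,
Rebaudioside C,C44H70O22,951.01,1,3,1.78,1.485,FALSE,rhamnose ring counted as a ring for R1/R2 scaling
Rebaudioside D,C50H80O28,1129.15,2,3,2.20,1.80,FALSE,
Rebaudioside E,C44H70O23,967.01,2,2,1.82,1.515,FALSE,
Rebaudioside F,C43H68O22,936.99,1,3,1.86,1.545,FALSE,contains a xylose ring
Rebaudioside M,C56H90O33,1291.29,3,3,2.56,2.07,FALSE,also known as Rebaudioside X
Rebaudioside N,C56H90O32,1275.29,3,3,2.64,2.13,FALSE,
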