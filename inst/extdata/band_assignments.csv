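label,moiety,center,window_lo,window_hi
O-C19=O bend,aglycone_core,740,700,780
artificial-sweetener marker,extraneous,869,850,950
C5-O5 stretch,glucose_ring,887,850,950
C11-C12 stretch,aglycone_core,898,850,950
C-C stretch (aglycone rings),aglycone_core,1040,1004,1075
C6-O6-H bend,glucose_ring,1192,1150,1250
H-C9-C11 stretch,aglycone_core,1204,1150,1250
C4-O4-H bend,glucose_ring,1215,1150,1250
C16-C17 stretch,aglycone_core,1670,1640,1690
C19=O stretch,aglycone_core,1738,1690,1760
C16=O stretch (linked carbonyl),linked_carbonyl,1738,1690,1760
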