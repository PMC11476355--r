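product,rings_c19,total_rings_1,total_rings_2
Morita 1,1.15,3.31,3.31
Morita 2,0.58,2.33,2.33
China 1,0.69,2.78,2.78
China 2,0.63,2.29,2.30
Fermented,0.61,2.30,2.31
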