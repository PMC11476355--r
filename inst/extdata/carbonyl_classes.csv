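class,rings_c19,center,provenance
0-ring,0,1706,printed
1-ring,1,1719,printed
2-ring,2,1728,interpolated
3-ring,3,1733,interpolated
linked,NA,1738,printed
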