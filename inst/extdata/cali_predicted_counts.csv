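scenario,n_added,covered,total
july,0,1017011,2258823
july,1,1585437,2258823
july,2,1696205,2258823
november,0,1574724,2258823
november,1,2063889,2258823
november,2,2194907,2258823
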