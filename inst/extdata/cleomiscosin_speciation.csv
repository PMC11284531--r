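compound,pka1,pH,pct_neutral,pct_anion
CMA,9.43,7.4,99.1,0.9
CMB,9.35,7.4,98.9,1.1
CMC,9.59,7.4,99.4,0.6
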