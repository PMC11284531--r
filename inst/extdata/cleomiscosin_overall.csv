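compound,medium,scenario,k_overall,tol_rel,note
CMA,gas,default,7.52e2,0.002,
CMB,gas,default,2.90e3,0.005,printed value rounds the branch sum 2.894e3 up
CMC,gas,default,6.28e4,0.002,
CMA,pentyl_ethanoate,default,1.06e3,0.002,
CMB,pentyl_ethanoate,default,3.47e2,0.002,
CMC,pentyl_ethanoate,default,6.44e4,0.002,branch sum 6.433e4 printed as 6.44e4
CMA,water,default,7.02e7,0.002,
CMB,water,default,8.66e7,0.002,
CMC,water,default,4.03e7,0.005,anion fraction limited by 2-decimal pKa
CMA,water,explicit_water,2.16e7,0.002,
CMB,water,explicit_water,1.43e7,0.002,
CMC,water,explicit_water,6.60e6,0.002,recomputed from branch values
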