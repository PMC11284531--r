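compound,medium,scenario,mechanism,protonation_state,site,dg_act,kappa,lambda,k,f,k_f,gamma,f_convention,tol_tst,tol_kf
CMA,gas,default,FHT,HA,O14-H,16.7,195.2,,7.29e2,1,7.29e2,96.9,printed,0.10,0.002
CMA,gas,default,FHT,HA,C18-H,18.6,153.0,,2.30e1,1,2.30e1,3.1,printed,0.10,0.002
CMB,gas,default,FHT,HA,O14-H,16.4,472.4,,2.84e3,1,2.84e3,98.1,printed,0.10,0.002
CMB,gas,default,FHT,HA,C17-H,18.3,209.3,,5.42e1,1,5.42e1,1.9,printed,0.10,0.002
CMC,gas,default,FHT,HA,O14-H,14.2,254.4,,6.28e4,1,6.28e4,100.0,printed,0.10,0.002
CMC,gas,default,FHT,HA,C18-H,20.1,912.1,,1.04e1,1,1.04e1,0.0,printed,0.10,0.002
CMA,pentyl_ethanoate,default,FHT,HA,O14-H,18.1,3224.1,,1.06e3,1,1.06e3,100.0,printed,0.10,0.002
CMA,pentyl_ethanoate,default,FHT,HA,C18-H,22.4,227.5,,5.91e-2,1,5.91e-2,0.0,printed,0.10,0.002
CMB,pentyl_ethanoate,default,FHT,HA,O14-H,18.6,2311.7,,3.47e2,1,3.47e2,100.0,printed,0.10,0.002
CMB,pentyl_ethanoate,default,FHT,HA,C17-H,22.6,258.6,,4.14e-2,1,4.14e-2,0.0,printed,0.10,0.002
CMC,pentyl_ethanoate,default,FHT,HA,O14-H,14.5,428.7,,6.43e4,1,6.43e4,100.0,printed,0.10,0.002
CMC,pentyl_ethanoate,default,FHT,HA,C18-H,19.3,743.7,,3.20e1,1,3.20e1,0.0,printed,0.10,0.002
CMA,water,default,FHT,HA,O14-H,16.6,1664.7,,6.99e3,0.991,6.93e3,0.0,printed,0.10,0.002
CMA,water,default,SET,HA,-,62.1,1,7.7,1.90e-33,0.991,1.88e-33,0.0,printed,0.10,0.002
CMA,water,default,SET,A_minus,O14-H,2.3,1,5.0,7.80e9,0.009,7.02e7,100.0,printed,,0.002
CMB,water,default,FHT,HA,O14-H,17.0,12304.8,,2.58e4,0.989,2.56e4,0.0,printed,0.10,0.005
CMB,water,default,SET,HA,-,59.7,1,8.1,1.00e-31,0.989,9.89e-32,0.0,printed,0.10,0.002
CMB,water,default,SET,A_minus,O14-H,2.4,1,5.4,7.80e9,0.011,8.66e7,100.0,full,,0.002
CMC,water,default,FHT,HA,O14-H,18.7,865.5,,1.13e2,0.994,1.12e2,0.0,printed,0.10,0.005
CMC,water,default,SET,HA,-,58.4,1,5.5,9.30e-31,0.994,9.24e-31,0.0,printed,0.10,0.002
CMC,water,default,SET,A_minus,O14-H,3.3,1,4.9,6.30e9,0.006,4.03e7,100.0,full,,0.005
CMA,water,explicit_water,FHT,HA,O14-H,16.6,1664.7,,6.99e3,0.991,6.93e3,0.0,printed,0.10,0.002
CMA,water,explicit_water,SET,HA,-,62.1,1,7.7,1.90e-33,0.991,1.88e-33,0.0,printed,0.10,0.002
CMA,water,explicit_water,SET,A_minus,O14-H,4.5,1,7.4,2.4e9,0.009,2.16e7,100.0,printed,,0.002
CMB,water,explicit_water,FHT,HA,O14-H,17.0,12304.8,,2.58e4,0.989,2.56e4,0.0,printed,0.10,0.005
CMB,water,explicit_water,SET,HA,-,59.7,1,8.1,1.00e-31,0.989,9.89e-32,0.0,printed,0.10,0.002
CMB,water,explicit_water,SET,A_minus,O14-H,4.9,1,6.5,1.30e9,0.011,1.43e7,100.0,printed,,0.002
CMC,water,explicit_water,FHT,HA,O14-H,18.7,865.5,,1.13e2,0.994,1.12e2,0.0,printed,0.10,0.005
CMC,water,explicit_water,SET,HA,-,58.4,1,5.5,9.30e-31,0.994,9.24e-31,0.0,printed,0.10,0.002
CMC,water,explicit_water,SET,A_minus,O14-H,5.0,1,8.1,1.10e9,0.006,6.60e6,100.0,printed,,0.002
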