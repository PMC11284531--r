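compound,site,medium,bde,dg_fht,pa,dg_pt,ie,dg_set
CMA,O14-H,gas,88.5,3.3,340.6,187.8,182.4,159.6
CMA,C18-H,gas,90.2,4.9,363.1,211.4,182.4,159.6
CMA,O19-H,gas,105.8,20.4,354.2,203.4,182.4,159.6
CMB,O14-H,gas,88.3,2.9,343.5,187.8,179.1,156.5
CMB,C17-H,gas,89.7,4.1,364.2,211.4,179.1,156.5
CMB,O19-H,gas,105.4,19.7,353.5,203.4,179.1,156.5
CMC,O14-H,gas,84.2,-1.5,334.6,183.1,179.3,155.9
CMC,C18-H,gas,86.3,0.1,358.2,205.8,179.3,155.9
CMC,O19-H,gas,106.1,20.6,364.0,211.7,179.3,155.9
CMA,O14-H,pentyl_ethanoate,86.0,0.5,308.3,105.9,146.2,75.2
CMA,C18-H,pentyl_ethanoate,90.9,5.7,337.3,135.4,146.2,75.2
CMA,O19-H,pentyl_ethanoate,104.9,19.5,324.7,123.9,146.2,75.2
CMB,O14-H,pentyl_ethanoate,85.9,0.9,309.1,107.0,144.6,74.3
CMB,C17-H,pentyl_ethanoate,90.9,6.0,338.1,136.5,144.6,74.3
CMB,O19-H,pentyl_ethanoate,104.8,19.7,324.0,122.6,144.6,74.3
CMC,O14-H,pentyl_ethanoate,84.0,-4.9,306.4,102.6,147.6,73.5
CMC,C18-H,pentyl_ethanoate,87.4,-0.7,333.0,128.7,147.6,73.5
CMC,O19-H,pentyl_ethanoate,105.8,18.2,328.5,125.6,147.6,73.5
CMA,O14-H,water,85.6,-3.2,43.7,36.9,110.9,31.4
CMA,C18-H,water,93.2,4.2,83.1,76.2,110.9,31.4
CMA,O19-H,water,107.0,18.0,56.0,49.4,110.9,31.4
CMB,O14-H,water,85.6,-3.5,43.8,36.7,110.7,30.9
CMB,C17-H,water,93.6,4.4,83.9,76.5,110.7,30.9
CMB,O19-H,water,107.1,17.8,55.9,49.2,110.7,30.9
CMC,O14-H,water,86.9,-1.4,43.7,37.4,117.6,38.2
CMC,C18-H,water,91.0,2.4,79.3,72.1,117.6,38.2
CMC,O19-H,water,107.1,19.4,58.9,52.3,117.6,38.2
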