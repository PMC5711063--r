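patient,target,correlation_pct,sim_max_mm,sim_min_mm,sim_mean_mm,sim_sd_mm,tgt_max_mm,tgt_min_mm,tgt_mean_mm,tgt_sd_mm,rate_pct,rate_sd_pct
1,diaphragm,90.4,8.9,6.4,7.67,0.73,4.3,0.4,1.92,0.92,75.0,12.0
2,diaphragm,95.7,8.3,2.6,6.05,1.32,3.5,0.4,1.60,0.8,73.6,13.2
3,diaphragm,98.5,36.1,15.7,21.39,5.7,9.6,2.2,7.00,1.99,67.3,9.3
4,diaphragm,98.5,12.2,1.8,9.50,1.88,3.5,0.9,2.44,0.62,74.3,6.5
5,hemostatic_clip,96.5,12.4,4.6,9.23,2.19,4.1,0.8,2.25,0.81,75.6,8.8
6,diaphragm,98.7,33.5,12.4,23.51,6.8,13.9,0.5,4.10,2.82,82.5,12.0
7,diaphragm,99.6,27.2,13.4,19.9,3.9,8.7,0.5,3.98,1.93,80.0,9.7
8,diaphragm,96.0,27.4,11.3,21.81,5.25,13.3,1.1,6.05,2.35,72.27,10.78
9,diaphragm,95.8,28.3,15.2,22.99,3.49,9.8,1.1,4.88,2.42,78.79,10.5
10,diaphragm,96.4,18.1,10.6,13.45,1.69,5.3,0.4,3.01,1.23,77.62,11.7
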