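patient,group,fem_count,lat_count,med_count,pat_count,fem_area,lat_area,med_area,pat_area
1,D,3,1,7,0,50.11,1.18,53.79,0.00
2,D,2,0,0,0,186.83,0.00,0.00,0.00
3,D,1,0,1,0,29.57,0.00,22.91,0.00
4,D,1,0,0,1,3.06,0.00,0.00,2.97
5,D,1,0,0,3,10.52,0.00,0.00,4.03
6,D,4,0,0,0,19.80,0.00,0.00,0.00
7,D,1,0,0,0,0.78,0.00,0.00,0.00
8,D,1,0,0,0,4.60,0.00,0.00,0.00
9,T,5,0,0,2,488.81,0.00,0.00,1.87
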