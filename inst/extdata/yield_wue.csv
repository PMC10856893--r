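year,treatment,yield_per_plant,yield_total,wue
2022,T1,1.28,56.50,38.18
2022,T2,1.14,49.06,40.83
2022,T3,1.01,43.39,42.22
2023,T1,1.30,54.11,26.60
2023,T2,1.13,48.21,31.39
2023,T3,0.96,40.92,33.22
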