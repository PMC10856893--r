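year,treatment,days_after_transplant,lai,plant_height,stem_diameter
2022,T1,32,0.43,54.78,9.49
2022,T1,42,0.94,81.60,10.33
2022,T1,52,2.30,133.9,12.10
2022,T1,62,3.54,142.8,12.54
2022,T1,72,3.69,141.8,12.78
2022,T1,87,3.51,140.1,12.95
2022,T2,32,0.54,54.03,9.24
2022,T2,42,0.85,74.80,10.31
2022,T2,52,1.50,116.2,11.61
2022,T2,62,2.36,125.6,11.95
2022,T2,72,2.64,127.0,12.19
2022,T2,87,2.53,129.8,12.30
2022,T3,32,0.41,55.08,9.37
2022,T3,42,0.61,68.17,10.22
2022,T3,52,1.23,104.6,11.01
2022,T3,62,2.00,120.5,11.28
2022,T3,72,2.36,122.0,11.54
2022,T3,87,2.31,122.2,11.77
2023,T1,30,0.53,54.63,8.89
2023,T1,40,1.00,86.23,9.31
2023,T1,50,2.07,128.67,10.00
2023,T1,60,3.27,136.67,12.24
2023,T1,70,3.58,139.67,12.65
2023,T1,80,3.65,140.50,12.67
2023,T2,30,0.56,54.67,8.77
2023,T2,40,0.86,81.67,9.39
2023,T2,50,1.44,103.50,10.56
2023,T2,60,2.19,115.38,11.18
2023,T2,70,2.57,118.00,11.74
2023,T2,80,2.64,126.17,11.81
2023,T3,30,0.61,56.00,8.81
2023,T3,40,0.85,77.95,9.10
2023,T3,50,1.29,99.88,10.21
2023,T3,60,1.99,110.80,10.97
2023,T3,70,2.33,113.17,11.04
2023,T3,80,2.39,119.67,11.41
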