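year,treatment,tss,vc,oa,ssc,sar
2022,T1,5.27,154.53,0.43,23.19,4.67
2022,T2,5.89,183.60,0.48,29.58,6.15
2022,T3,6.60,172.42,0.50,30.42,6.51
2023,T1,4.64,130.70,0.48,21.02,4.18
2023,T2,5.25,153.88,0.54,25.33,4.80
2023,T3,5.45,154.67,0.55,26.07,4.89
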