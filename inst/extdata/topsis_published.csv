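year,treatment,d_plus,d_minus,ci,rank
2022,T1,0.8844,0.4667,0.3454,3
2022,T2,0.4008,0.6942,0.6340,1
2022,T3,0.4966,0.8131,0.6209,2
2023,T1,0.8866,0.4624,0.3428,3
2023,T2,0.2706,0.7821,0.7429,1
2023,T3,0.4624,0.8866,0.6572,2
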