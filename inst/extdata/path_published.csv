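stage,variable,direct,correlation
flowering_fruit_setting,DAR,0.057,0.795
flowering_fruit_setting,W,0.144,0.255
flowering_fruit_setting,VPD,0.810,0.864
flowering_fruit_setting,Ta,0.087,0.384
flowering_fruit_setting,LAI,0.414,0.405
picking,DAR,0.738,0.888
picking,W,0.246,0.520
picking,VPD,0.085,0.583
picking,Ta,0.025,0.421
picking,LAI,0.029,-0.183
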