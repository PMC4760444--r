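variable,pre_mean,pre_se,post_mean,post_se,p
fb,12.6,1.6,13.9,1.0,0.39
vt,1.0,0.1,0.94,0.1,0.54
ve,11.0,1.1,12.7,0.5,0.18
peto2,101.8,1.8,105.6,2.0,0.27
petco2,41.4,1.2,39.5,0.7,0.13
spo2,96.4,0.3,97.1,0.3,0.10
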