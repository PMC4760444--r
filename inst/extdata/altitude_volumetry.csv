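subject,gm_pre_ml,gm_post_ml,gm_pct_change,wm_pre_ml,wm_post_ml,wm_pct_change,wmhi_pre,wmhi_post
1,733,718,-2.1,666,652,-2.0,3,6
2,569,544,-4.3,509,490,-3.7,1,1
3,653,631,-3.4,614,623,1.5,3,4
4,686,670,-2.4,659,659,0.0,38,37
5,701,689,-1.6,643,633,-1.5,NA,NA
6,667,653,-2.0,601,590,-1.8,0,0
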