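subject,gm_pre,gm_post,gm_pct_change,wm_pre,wm_post,wm_pct_change
1,0.30,0.39,31.5,0.27,0.20,-25.8
2,0.34,0.42,21.3,0.19,0.21,8.8
3,0.27,0.31,15.2,0.15,0.18,20.6
4,0.31,0.23,-24.3,0.12,0.16,28.9
5,0.33,0.41,24.8,0.19,0.22,16.5
6,0.31,0.32,3.1,0.17,0.15,-7.1
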