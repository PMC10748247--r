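subject,pp_nrs,easi,scratch_time_video_s,scratch_frac_video,scratch_time_sigma_s,scratch_frac_sigma,sensitivity,specificity,accuracy,precision,npv,event_tp_frac
S3,2,8,77,0.04,262,0.14,0.21,0.86,0.82,0.09,0.98,0.89
S4,5,16.4,72,0.04,186,0.9,0.52,0.92,0.91,0.23,0.98,1
S5,8,23.5,92,0.05,184,0.1,NA,0.9,0.9,0,1,0
S6,3,8.2,31,0.02,270,0.15,0.41,0.86,0.85,0.06,0.99,0.94
S7,5,8.2,20,0.01,815,0.45,0.47,0.55,0.55,0.01,1,0.5
S8,5,14.4,20,0.01,104,0.05,NA,0.94,0.94,0,1,0
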