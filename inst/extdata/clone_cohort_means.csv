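clone,sigma1_mean,sigma1_sem,sigma2_mean,sigma2_sem,p_paired,ratio_sigma,ratio_F
L,5.5,0.4,5.8,0.4,0.59,1.05,1.52
M,10.4,1.0,10.6,1.0,0.89,1.02,1.54
H,5.3,0.4,5.8,0.4,0.39,1.09,1.56
HH,5.4,0.4,5.7,0.2,0.51,1.06,1.51
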