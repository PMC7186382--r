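type,dv0_mean,dv0_sd,d_mean,d_sd
inertia_increase,-12,5,-2.0,1.0
inertia_decrease,10,5,1.0,1.0
damping_increase,-15,5,1.5,1.0
damping_decrease,15,5,-1.0,1.0
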