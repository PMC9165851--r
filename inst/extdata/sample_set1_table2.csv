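sample_id,cryotem_pct_full,vg_per_fraction,cp_per_fraction,vgcp_printed_pct
S1.1,2,1.79e14,3.49e15,5
S1.2,5,1.73e14,3.75e15,5
S1.3,10,1.28e14,1.35e15,9
S1.4,11,1.42e14,8.50e14,17
S1.5,18,1.16e14,5.25e14,22
S1.6,26,7.24e13,2.89e14,25
S1.7,43,4.25e13,6.19e13,69
S1.8,59,5.40e13,6.47e13,84
S1.9,70,7.81e13,1.06e14,74
S1.10,79,4.59e14,3.81e14,120
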