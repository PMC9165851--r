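sample_id,theoretical_pct_full,invitro_bp,invivo_bp,imaging
S2.1,79.32,1.61,7.70,CryoTEM
S2.2,71.30,1.33,6.63,CryoTEM
S2.3,61.28,1.37,6.07,CryoTEM
S2.4,41.24,0.74,3.15,CryoTEM
S2.5,1.17,0.00,0.20,CryoTEM/nsTEM
S2.6,NA,NA,NA,nsTEM
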