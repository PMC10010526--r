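material,density_g_cm3
water,1
soft_tissue,1.06
bone,1.92
pmma,1.19
al,2.699
ti,4.506
cu,8.96
air,0.001205
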