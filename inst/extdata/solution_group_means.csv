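metric,dap,sensitive,tolerant,lsd_05
crown_roots,0,12.4,14.0,
crown_roots,1,2.5,3.5,0.9
crown_roots,3,8.8,10.7,1.0
total_zn_ug,0,1.11,1.33,0.18
total_zn_ug,13,1.23,1.53,0.28
root_zn_conc_ug_per_g,0,49.1,55.6,4.4
root_zn_conc_ug_per_g,13,24.7,22.6,
shoot_zn_conc_ug_per_g,0,36.8,39.9,2.9
shoot_zn_conc_ug_per_g,13,14.4,12.5,
root_zn_ug,13,0.27,0.45,
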