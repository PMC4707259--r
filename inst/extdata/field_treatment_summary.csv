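treatment,dat,total_dw_mg,total_dw_se,shoot_zn_ug_per_g,shoot_zn_se
minusZn,7,60.3,2.3,31.1,1.7
minusZn,15,144.7,6.9,11.3,0.3
minusZn,21,262.4,22.7,11.9,0.5
minusZn,28,608.7,81.0,12.8,0.5
plusZn,7,58.7,2.2,37.9,1.3
plusZn,15,218.8,8.3,23.6,0.5
plusZn,21,709.2,47.7,24.7,1.0
plusZn,28,2549.9,210.0,22.9,0.4
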