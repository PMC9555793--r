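# Reference diagnostic rules matched by the five worked evaluation cases
LSD(<=100) & L4(<10) & LL3(<75) => Category(4) | conf=66.667
LL3(<85;91)) & H_An(>=8) & H_EffLife(>=8) & H_Sv(>=7.5) => Category(3) | conf=100
LR8(>=999) & R6(>=75) & T_Sv(>=8) => Category(2) | conf=96.2
LL3(<15;20)) & T_An(>=8) => Category(1) | conf=94.4
E14(yes) & E22(yes) => Category(1) | conf=60.3
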