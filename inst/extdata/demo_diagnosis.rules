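# Sample mined diagnostic decision rules (interview + audiometry -> TRT category)
R3(<15;20)) & T_An(>=8) => Category(1) | conf=94
H_pr(<0;0.5)) & HL_pr(<0;0.5)) & T_pr(<6;8)) => Category(1) | conf=85
L2(>=50) & R6(<=75) => Category(2) | conf=87
Norvasc(yes) & T_side(yes) => Category(2) | conf=67
T_pr(<0;2.5)) & H_An(<1.5;3.5)) & H_Sv(<1.5;3.5)) => Category(3) | conf=83
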