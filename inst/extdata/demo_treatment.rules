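# Sample mined treatment action rules (stable context : flexible change -> improvement)
G(m) & NTI(yes) : (Ins(GHH->GHS)) => Ch(better) | conf=80
T_side(yes) & OMTI(yes) : (Ins(GHH->V) & FU(0->T)) => Ch(better) | conf=82
Ins(SG) : (Mix_RSL(<11;12)-><9;10))) => Ch(better) | conf=100
FU(A) & Ins(GHI) & Freq_LE(<3000;3150)) : (treat(<5;6)-><6;8))) => Ch(better) | conf=88
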