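# Reference treatment action rules matched by the worked evaluation cases
G(m) & NTI(yes) : (Ins(GHH->GHS)) => Ch(better) | conf=80 ; gain=41
Cat(C1) : (Ins(GHS->GHI) & treat(<22;52)-><9;14))) => Ch(better) | conf=85 ; gain=34.8
Ins(GHS) : (Freq_LE(<2800;3000)-><2670;2800))) => Ch(better) | conf=75 ; gain=8.4
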