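case,field,value
1,actual,C4
1,protocol,C4
1,G,m
1,age,38
1,state,KY
1,NTI,yes
1,LSD,100
1,L4,5
1,LL3,70
1,Ins,GHH
1,Cat,C4
2,actual,C3
2,protocol,C3
2,G,m
2,age,49
2,state,GA
2,OTI,yes
2,LL3,88
2,H_An,9
2,H_EffLife,9
2,H_Sv,8
2,Cat,C3
3,actual,C2
3,protocol,C2
3,G,f
3,age,77
3,state,FL
3,HLTI,yes
3,LR8,999
3,R6,78
3,T_Sv,9
3,Ins,HA
3,Cat,C2
4,actual,C1
4,protocol,C1
4,G,m
4,age,53
4,state,GA
4,STI,yes
4,LL3,17
4,T_An,9
4,Ins,GHS
4,treat,24
4,Cat,C1
5,actual,C0
5,protocol,C1
5,note,interview and audiometric data flagged as inconsistent at the source
5,G,m
5,age,36
5,state,GA
5,AATI,yes
5,E14,yes
5,E22,yes
5,Ins,GHS
5,Freq_LE,2900
5,Cat,C0
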