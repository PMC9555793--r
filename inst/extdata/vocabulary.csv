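"name","kind","dtype","units","domain","phrase","value_phrases"
"R1","stable","numeric","dB HL","-10:120","the right-ear pure-tone threshold at 1 kHz",""
"L1","stable","numeric","dB HL","-10:120","the left-ear pure-tone threshold at 1 kHz",""
"R2","stable","numeric","dB HL","-10:120","the right-ear pure-tone threshold at 2 kHz",""
"L2","stable","numeric","dB HL","-10:120","the left-ear pure-tone threshold at 2 kHz",""
"R3","stable","numeric","dB HL","-10:120","the right-ear pure-tone threshold at 3 kHz",""
"L3","stable","numeric","dB HL","-10:120","the left-ear pure-tone threshold at 3 kHz",""
"R4","stable","numeric","dB HL","-10:120","the right-ear pure-tone threshold at 4 kHz",""
"L4","stable","numeric","dB HL","-10:120","the left-ear pure-tone threshold at 4 kHz",""
"R6","stable","numeric","dB HL","-10:120","the right-ear pure-tone threshold at 6 kHz",""
"L6","stable","numeric","dB HL","-10:120","the left-ear pure-tone threshold at 6 kHz",""
"R8","stable","numeric","dB HL","-10:120","the right-ear pure-tone threshold at 8 kHz",""
"L8","stable","numeric","dB HL","-10:120","the left-ear pure-tone threshold at 8 kHz",""
"R12","stable","numeric","dB HL","-10:120","the right-ear pure-tone threshold at 12 kHz",""
"L12","stable","numeric","dB HL","-10:120","the left-ear pure-tone threshold at 12 kHz",""
"LR1","stable","numeric","dB","0:999","the right-ear loudness discomfort level at 1 kHz",""
"LL1","stable","numeric","dB","0:999","the left-ear loudness discomfort level at 1 kHz",""
"LR2","stable","numeric","dB","0:999","the right-ear loudness discomfort level at 2 kHz",""
"LL2","stable","numeric","dB","0:999","the left-ear loudness discomfort level at 2 kHz",""
"LR3","stable","numeric","dB","0:999","the right-ear loudness discomfort level at 3 kHz",""
"LL3","stable","numeric","dB","0:999","the left-ear loudness discomfort level at 3 kHz",""
"LR4","stable","numeric","dB","0:999","the right-ear loudness discomfort level at 4 kHz",""
"LL4","stable","numeric","dB","0:999","the left-ear loudness discomfort level at 4 kHz",""
"LR5","stable","numeric","dB","0:999","the right-ear loudness discomfort level at 5 kHz",""
"LL5","stable","numeric","dB","0:999","the left-ear loudness discomfort level at 5 kHz",""
"LR6","stable","numeric","dB","0:999","the right-ear loudness discomfort level at 6 kHz",""
"LL6","stable","numeric","dB","0:999","the left-ear loudness discomfort level at 6 kHz",""
"LR7","stable","numeric","dB","0:999","the right-ear loudness discomfort level at 7 kHz",""
"LL7","stable","numeric","dB","0:999","the left-ear loudness discomfort level at 7 kHz",""
"LR8","stable","numeric","dB","0:999","the right-ear loudness discomfort level at 8 kHz",""
"LL8","stable","numeric","dB","0:999","the left-ear loudness discomfort level at 8 kHz",""
"Th_R","stable","numeric","dB HL","-10:120","the right-ear hearing threshold",""
"Th_L","stable","numeric","dB HL","-10:120","the left-ear hearing threshold",""
"T_LR","stable","numeric","dB","0:120","the right-ear tinnitus loudness match",""
"LSD","stable","numeric","","0:10000","LSD",""
"T_pr","stable","ordinal_0_10","score points","0:10","tinnitus as a problem",""
"H_pr","stable","ordinal_0_10","score points","0:10","hyperacusis as a problem",""
"HL_pr","stable","ordinal_0_10","score points","0:10","hearing loss as a problem",""
"T_An","stable","ordinal_0_10","score points","0:10","annoyance over tinnitus",""
"T_Sv","stable","ordinal_0_10","score points","0:10","severity of tinnitus",""
"H_An","stable","ordinal_0_10","score points","0:10","annoyance over hyperacusis",""
"H_Sv","stable","ordinal_0_10","score points","0:10","severity of hyperacusis",""
"H_EffLife","stable","ordinal_0_10","score points","0:10","effect of hyperacusis on life",""
"E14","stable","binary","","","often irritable because of tinnitus",""
"E22","stable","binary","","","tinnitus makes the patient anxious",""
"STI","stable","binary","","","stress-induced tinnitus",""
"NTI","stable","binary","","","noise-induced tinnitus","yes=whose tinnitus was induced by noise|no=whose tinnitus was not induced by noise"
"HLTI","stable","binary","","","hearing-loss-induced tinnitus","yes=whose tinnitus was induced by hearing loss"
"DETI","stable","binary","","","depression-related tinnitus","yes=whose tinnitus is depression-related"
"AATI","stable","binary","","","auto-accident-related tinnitus","yes=whose tinnitus followed an auto accident"
"OTI","stable","binary","","","surgery-related tinnitus","yes=whose tinnitus followed surgery"
"OMTI","stable","binary","","","tinnitus induced by another medical condition","yes=whose tinnitus was induced by another medical condition"
"T_side","stable","binary","","","tinnitus as a medication side effect",""
"Norvasc","stable","binary","","","intake of Norvasc",""
"Lipitor","stable","binary","","","intake of Lipitor",""
"G","stable","categorical","","m|f","gender","m=a male|f=a female"
"state","stable","categorical","","","state of residence",""
"age","stable","numeric","years","0:120","age",""
"AgeInd","stable","numeric","years","0:120","age when tinnitus was induced",""
"AgeBeg","stable","numeric","years","0:120","age when treatment began",""
"DTI","stable","numeric","years","0:100","years since tinnitus was induced",""
"Cat","stable","categorical","","C0|C1|C2|C3|C4","the TRT category","C0=a patient in Category 0|C1=a patient in Category 1|C2=a patient in Category 2|C3=a patient in Category 3|C4=a patient in Category 4"
"Ins","flexible","categorical","","HA|SG|GHI|GHH|GHS|V|combination|none","the sound instrument",""
"FU","flexible","categorical","","A|C|T|E|0","the follow-up contact type",""
"Mix_RSL","flexible","numeric","dB","0:60","the mixing point for the right ear",""
"Freq_LE","flexible","numeric","Hz","100:16000","the left-ear REM frequency response",""
"treat","flexible","numeric","weeks","0:520","the treatment duration",""
"Tsc","flexible","numeric","score points","0:100","the THI total score",""
"Taw","flexible","ordinal_0_10","score points","0:10","tinnitus awareness",""
"ChTsc","decision","numeric","score points","-100:100","the change in THI total score since the previous visit",""
"PerChTsc","decision","numeric","percent","-10000:10000","the percent change in THI total score since the previous visit",""
"ChTaw","decision","numeric","score points","-10:10","the change in tinnitus awareness since the previous visit",""
"PerChTaw","decision","numeric","percent","-10000:10000","the percent change in tinnitus awareness since the previous visit",""
"Ch","decision","categorical","","better|same|worse","the treatment outcome",""
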