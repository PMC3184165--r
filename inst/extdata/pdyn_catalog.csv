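name,sequence,c_term_amide,precursor,range_start,range_end,note
Leu-Enk,YGGFL,FALSE,aNeo,1,5,commonly printed as m/z 555; computed [M+H]+ 556.28
Leu-Enk-Arg,YGGFLR,FALSE,Dyn B,1,6,
Leu-Enk-Arg-Arg,YGGFLRR,FALSE,Dyn A(1-17),1,7,commonly printed as m/z 867; computed [M+H]+ 868.48
aNeo(1-7),YGGFLRK,FALSE,aNeo,1,7,
aNeo,YGGFLRKYPK,FALSE,,,,
bNeo,YGGFLRKYP,FALSE,aNeo,1,9,
Dyn A(1-8),YGGFLRRI,FALSE,Dyn A(1-17),1,8,
Dyn A(1-17),YGGFLRRIRPKLKWDNQ,FALSE,,,,commonly printed as m/z 2145; computed [M+H]+ 2147.20
Dyn A(10-17),PKLKWDNQ,FALSE,Dyn A(1-17),10,17,
Dyn B,YGGFLRRQFKVVT,FALSE,,,,
Substance P,RPKPQQFFGLM,TRUE,,,,
Dyn A(1-8)(2-8),GGFLRRI,FALSE,Dyn A(1-8),2,8,des-Tyr metabolite
aNeo(2-10),GGFLRKYPK,FALSE,aNeo,2,10,des-Tyr metabolite
Dyn B(2-13),GGFLRRQFKVVT,FALSE,Dyn B,2,13,des-Tyr metabolite
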