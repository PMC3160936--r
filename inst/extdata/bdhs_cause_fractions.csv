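wave,denominator,age_group,cause,fraction,lo,hi
1993-1994,under5,all,pneumonia,0.29,0.25,0.34
1996-1997,under5,all,pneumonia,0.24,0.20,0.29
2004,under5,all,pneumonia,0.33,0.28,0.39
1993-1994,under5,all,birth_asphyxia_birth_injury,0.03,0.02,0.05
1996-1997,under5,all,birth_asphyxia_birth_injury,0.06,0.04,0.09
2004,under5,all,birth_asphyxia_birth_injury,0.13,0.10,0.17
1993-1994,under5,all,prematurity_lbw,0.03,0.02,0.05
1996-1997,under5,all,prematurity_lbw,0.04,0.02,0.07
2004,under5,all,prematurity_lbw,0.10,0.07,0.15
1993-1994,under5,neonate,pneumonia,0.09,0.06,0.12
1996-1997,under5,neonate,pneumonia,0.08,0.05,0.11
2004,under5,neonate,pneumonia,0.12,0.09,0.17
1993-1994,under5,postneonate,pneumonia,0.20,0.16,0.25
1996-1997,under5,postneonate,pneumonia,0.16,0.12,0.20
2004,under5,postneonate,pneumonia,0.21,0.16,0.26
1993-1994,under5,postneonate,diarrhea,0.10,0.06,0.13
1996-1997,under5,postneonate,diarrhea,0.11,0.07,0.14
2004,under5,postneonate,diarrhea,0.06,0.03,0.09
1993-1994,under5,postneonate,measles,0.04,0.02,0.06
2004,under5,postneonate,measles,0.002,0.00,0.009
1993-1994,under5,postneonate,injury,0.09,0.05,0.13
1996-1997,under5,postneonate,injury,0.07,0.04,0.09
2004,under5,postneonate,injury,0.04,0.02,0.08
1993-1994,under5,postneonate,malnutrition,0.07,0.05,0.10
1996-1997,under5,postneonate,malnutrition,0.08,0.05,0.11
2004,under5,postneonate,malnutrition,0.06,0.03,0.10
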