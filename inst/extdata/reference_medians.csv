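# Median organ equivalent doses (mSv) by protocol, sex and BEIR VII
# category, plus gender-neutral effective dose, as published by the
# reference dosimetry-software comparison study (adult CT protocols,
# modal tube voltage 120 kV).  printed_difference_msv is the study's
# printed NCICT-minus-ImPACT difference column.
protocol,sex,site,n_cases,impact_msv,ncict_msv,printed_difference_msv
abdomen_pelvis,male,stomach,160,14.00,12.70,-1.30
abdomen_pelvis,male,colon,160,12.00,14.85,2.85
abdomen_pelvis,male,liver,160,13.00,12.04,-0.96
abdomen_pelvis,male,lung,160,2.35,3.09,0.74
abdomen_pelvis,male,prostate,160,12.00,6.31,-5.69
abdomen_pelvis,male,bladder,160,12.00,12.48,0.48
abdomen_pelvis,male,other,160,5.91,5.57,-0.34
abdomen_pelvis,male,thyroid,160,0.04,0.26,0.22
abdomen_pelvis,male,leukaemia,160,5.30,5.69,0.39
abdomen_pelvis,female,stomach,160,14.00,15.70,1.70
abdomen_pelvis,female,colon,160,12.00,16.30,4.30
abdomen_pelvis,female,liver,160,13.00,15.07,2.07
abdomen_pelvis,female,lung,160,2.35,3.10,0.75
abdomen_pelvis,female,breast,160,0.51,1.17,0.66
abdomen_pelvis,female,uterus,160,13.00,9.68,-3.32
abdomen_pelvis,female,ovary,160,12.00,10.29,-1.71
abdomen_pelvis,female,bladder,160,12.00,13.88,1.88
abdomen_pelvis,female,other,160,6.21,6.70,0.48
abdomen_pelvis,female,thyroid,160,0.04,0.26,0.22
abdomen_pelvis,female,leukaemia,160,5.30,6.50,1.20
abdomen_pelvis,neutral,effective_dose,160,6.70,7.51,0.81
chest,male,stomach,155,4.00,9.55,5.55
chest,male,colon,155,0.16,2.88,2.72
chest,male,liver,155,5.80,9.36,3.56
chest,male,lung,155,12.00,10.23,-1.77
chest,male,prostate,155,0.01,0.02,0.01
chest,male,bladder,155,0.01,0.04,0.03
chest,male,other,155,4.45,5.15,0.70
chest,male,thyroid,155,2.00,13.29,11.29
chest,male,leukaemia,155,3.50,2.91,-0.59
chest,female,stomach,155,4.00,6.68,2.68
chest,female,colon,155,0.16,0.48,0.32
chest,female,liver,155,5.80,11.57,5.77
chest,female,lung,155,12.00,12.70,0.70
chest,female,breast,155,9.60,11.73,2.13
chest,female,uterus,155,0.04,0.05,0.01
chest,female,ovary,155,0.05,0.06,0.01
chest,female,bladder,155,0.01,0.04,0.03
chest,female,other,155,4.72,6.65,1.93
chest,female,thyroid,155,2.00,15.74,13.74
chest,female,leukaemia,155,3.50,4.11,0.61
chest,neutral,effective_dose,155,5.10,6.49,1.39
head,male,stomach,124,0.00,0.05,0.04
head,male,colon,124,0.00,0.02,0.02
head,male,liver,124,0.01,0.06,0.05
head,male,lung,124,0.09,0.27,0.18
head,male,prostate,124,0.00,0.00,0.00
head,male,bladder,124,0.00,0.00,0.00
head,male,other,124,7.80,5.83,-1.98
head,male,thyroid,124,1.70,1.14,-0.56
head,male,leukaemia,124,2.60,2.22,-0.38
head,female,stomach,124,0.00,0.04,0.04
head,female,colon,124,0.00,0.01,0.01
head,female,liver,124,0.01,0.06,0.06
head,female,lung,124,0.09,0.34,0.25
head,female,breast,124,0.03,0.19,0.17
head,female,uterus,124,0.00,0.01,0.01
head,female,ovary,124,0.00,0.01,0.01
head,female,bladder,124,0.00,0.01,0.00
head,female,other,124,8.26,5.77,-2.49
head,female,thyroid,124,1.70,1.57,-0.13
head,female,leukaemia,124,2.60,1.86,-0.74
head,neutral,effective_dose,124,1.80,1.32,-0.48
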