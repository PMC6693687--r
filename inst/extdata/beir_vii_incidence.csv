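# BEIR VII Table 12D-1: lifetime attributable risk of cancer incidence,
# cases per 100,000 persons exposed to a single dose of 0.1 Gy, by sex,
# cancer site and age at exposure.  Transcribed from the public report.
sex,site,age,coefficient
male,stomach,0,76
male,stomach,5,65
male,stomach,10,55
male,stomach,15,46
male,stomach,20,40
male,stomach,30,28
male,stomach,40,27
male,stomach,50,25
male,stomach,60,20
male,stomach,70,14
male,stomach,80,7
male,colon,0,336
male,colon,5,285
male,colon,10,241
male,colon,15,204
male,colon,20,173
male,colon,30,125
male,colon,40,122
male,colon,50,113
male,colon,60,94
male,colon,70,65
male,colon,80,30
male,liver,0,61
male,liver,5,50
male,liver,10,43
male,liver,15,36
male,liver,20,30
male,liver,30,22
male,liver,40,21
male,liver,50,19
male,liver,60,14
male,liver,70,8
male,liver,80,3
male,lung,0,314
male,lung,5,261
male,lung,10,216
male,lung,15,180
male,lung,20,149
male,lung,30,105
male,lung,40,104
male,lung,50,101
male,lung,60,89
male,lung,70,65
male,lung,80,34
male,prostate,0,93
male,prostate,5,80
male,prostate,10,67
male,prostate,15,57
male,prostate,20,48
male,prostate,30,35
male,prostate,40,35
male,prostate,50,33
male,prostate,60,26
male,prostate,70,14
male,prostate,80,5
male,bladder,0,209
male,bladder,5,177
male,bladder,10,150
male,bladder,15,127
male,bladder,20,108
male,bladder,30,79
male,bladder,40,79
male,bladder,50,76
male,bladder,60,66
male,bladder,70,47
male,bladder,80,23
male,other,0,1123
male,other,5,672
male,other,10,503
male,other,15,394
male,other,20,312
male,other,30,198
male,other,40,172
male,other,50,140
male,other,60,98
male,other,70,57
male,other,80,23
male,thyroid,0,115
male,thyroid,5,76
male,thyroid,10,50
male,thyroid,15,33
male,thyroid,20,21
male,thyroid,30,9
male,thyroid,40,3
male,thyroid,50,1
male,thyroid,60,0.3
male,thyroid,70,0.1
male,thyroid,80,0
male,leukaemia,0,237
male,leukaemia,5,149
male,leukaemia,10,120
male,leukaemia,15,105
male,leukaemia,20,96
male,leukaemia,30,84
male,leukaemia,40,84
male,leukaemia,50,84
male,leukaemia,60,82
male,leukaemia,70,73
male,leukaemia,80,48
female,stomach,0,101
female,stomach,5,85
female,stomach,10,72
female,stomach,15,61
female,stomach,20,52
female,stomach,30,36
female,stomach,40,35
female,stomach,50,32
female,stomach,60,27
female,stomach,70,19
female,stomach,80,11
female,colon,0,220
female,colon,5,187
female,colon,10,158
female,colon,15,134
female,colon,20,114
female,colon,30,82
female,colon,40,79
female,colon,50,73
female,colon,60,62
female,colon,70,45
female,colon,80,23
female,liver,0,28
female,liver,5,23
female,liver,10,20
female,liver,15,16
female,liver,20,14
female,liver,30,10
female,liver,40,10
female,liver,50,9
female,liver,60,7
female,liver,70,5
female,liver,80,2
female,lung,0,733
female,lung,5,608
female,lung,10,504
female,lung,15,417
female,lung,20,346
female,lung,30,242
female,lung,40,240
female,lung,50,230
female,lung,60,201
female,lung,70,147
female,lung,80,77
female,breast,0,1171
female,breast,5,914
female,breast,10,712
female,breast,15,553
female,breast,20,429
female,breast,30,253
female,breast,40,141
female,breast,50,70
female,breast,60,31
female,breast,70,12
female,breast,80,4
female,uterus,0,50
female,uterus,5,42
female,uterus,10,36
female,uterus,15,30
female,uterus,20,26
female,uterus,30,18
female,uterus,40,16
female,uterus,50,13
female,uterus,60,9
female,uterus,70,5
female,uterus,80,2
female,ovary,0,104
female,ovary,5,87
female,ovary,10,73
female,ovary,15,60
female,ovary,20,50
female,ovary,30,34
female,ovary,40,31
female,ovary,50,25
female,ovary,60,18
female,ovary,70,11
female,ovary,80,5
female,bladder,0,212
female,bladder,5,180
female,bladder,10,152
female,bladder,15,129
female,bladder,20,109
female,bladder,30,79
female,bladder,40,78
female,bladder,50,74
female,bladder,60,64
female,bladder,70,47
female,bladder,80,24
female,other,0,1339
female,other,5,719
female,other,10,523
female,other,15,409
female,other,20,323
female,other,30,207
female,other,40,181
female,other,50,148
female,other,60,109
female,other,70,68
female,other,80,30
female,thyroid,0,634
female,thyroid,5,419
female,thyroid,10,275
female,thyroid,15,178
female,thyroid,20,113
female,thyroid,30,41
female,thyroid,40,14
female,thyroid,50,4
female,thyroid,60,1
female,thyroid,70,0.3
female,thyroid,80,0
female,leukaemia,0,185
female,leukaemia,5,112
female,leukaemia,10,86
female,leukaemia,15,76
female,leukaemia,20,71
female,leukaemia,30,63
female,leukaemia,40,62
female,leukaemia,50,62
female,leukaemia,60,57
female,leukaemia,70,51
female,leukaemia,80,37
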