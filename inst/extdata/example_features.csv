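feature_id,mz,rt,ion_mode,lab_1,lab_2,lab_3,ctl_1,ctl_2,ctl_3
ex01,183.1391,612,neg,303871,255545,287287,351538,354745,300392
ex02,194.2081,610.5,neg,15286,14484,9650,0,0,0
ex03,210.2443,562.8,neg,103157,89160,80648,63735,112217,93393
ex04,174.404,267.8,neg,62658,53567,50215,57990,62599,54460
ex05,310.1245,648.5,neg,371511,263035,374836,295770,311971,287789
ex06,737.7681,207,neg,26471,31225,39326,29185,29053,32297
ex07,385.2486,988.6,neg,135069,127830,106837,106322,92581,89359
ex08,878.2088,453.3,neg,25798,19934,29954,25669,20908,23362
ex09,249.3673,711.6,neg,22076,18459,18020,21174,13682,17722
ex10,478.1009,436.2,neg,21336,20187,18926,21824,14540,17834
ex11,253.9635,997.4,neg,30448,47292,39887,39505,31026,25931
ex12,300.5521,924.8,neg,176424,162104,262312,232747,166765,209675
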