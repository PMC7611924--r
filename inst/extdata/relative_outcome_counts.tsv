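relative	outcome	cases	total
father	alive	103919	450333
father	alzheimers_dementia	19255	399793
father	bowel_cancer	23883	399920
father	bronchitis_emphysema	46263	402389
father	diabetes	38850	400687
father	heart_disease	133320	407557
father	high_blood_pressure	91242	402899
father	lung_cancer	37443	401624
father	parkinsons	10106	399089
father	prostate_cancer	30945	399670
father	severe_depression	15430	399499
father	stroke	62810	402616
mother	alive	180472	454999
mother	alzheimers_dementia	36548	423738
mother	bowel_cancer	22028	423135
mother	breast_cancer	35102	423458
mother	bronchitis_emphysema	25314	423692
mother	diabetes	40091	423892
mother	heart_disease	85620	426240
mother	high_blood_pressure	130948	426391
mother	lung_cancer	17566	423258
mother	parkinsons	6998	422464
mother	severe_depression	28351	423217
mother	stroke	60880	424977
sibling	alzheimers_dementia	2094	361264
sibling	bowel_cancer	8920	361508
sibling	breast_cancer	16586	361809
sibling	bronchitis_emphysema	10325	361823
sibling	diabetes	31073	362826
sibling	heart_disease	37858	363542
sibling	high_blood_pressure	77059	364661
sibling	lung_cancer	8199	361586
sibling	parkinsons	2005	361199
sibling	prostate_cancer	5952	361394
sibling	severe_depression	26368	362315
sibling	stroke	12031	361925
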