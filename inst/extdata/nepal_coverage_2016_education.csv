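indicator,year,stratum_type,stratum,coverage
cpr_modern,2016,education,primary+,34.1
cpr_modern,2016,education,none,48.8
unmet_need,2016,education,primary+,28.2
unmet_need,2016,education,none,20.6
fp_need_satisfied,2016,education,primary+,54.7
fp_need_satisfied,2016,education,none,70.3
anc_skilled,2016,education,primary+,90.2
anc_skilled,2016,education,none,80.8
td2plus,2016,education,primary+,73
td2plus,2016,education,none,57.8
sba,2016,education,primary+,78
sba,2016,education,none,47.8
bcg,2016,education,primary+,98.6
bcg,2016,education,none,96.4
dpt3,2016,education,primary+,90
dpt3,2016,education,none,82.2
msl,2016,education,primary+,94.3
msl,2016,education,none,86.8
all_basic_vacc,2016,education,primary+,85.1
all_basic_vacc,2016,education,none,71
vitamin_a,2016,education,primary+,84.2
vitamin_a,2016,education,none,81.2
ort,2016,education,primary+,70.6
ort,2016,education,none,55.3
cpnm,2016,education,primary+,82.5
cpnm,2016,education,none,87
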