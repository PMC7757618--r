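region,population_baseline_thousands,tgr_baseline_percent,affected_baseline_thousands,population_endpoint_thousands,tgr_endpoint_percent,affected_endpoint_thousands,doing_nothing_cases_thousands,prevented_cases_thousands,prevalence_reduction_percent
Africa,543705,15.6,85029,929856,4.8,44716,145419,100703,69.3
Americas,691115,11.0,75832,970166,1.7,16931,106451,89520,84.1
Eastern Mediterranean,383635,24.2,93004,577938,3.9,22808,140109,117301,83.7
Europe,782151,12.8,100152,907895,5.1,46099,116253,70154,60.3
South Asia,1331968,13.0,172505,1878262,2.8,51829,243256,191427,78.7
East Asia and Pacific,1403931,10.5,147028,1853008,2.3,42978,194058,151081,77.9
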