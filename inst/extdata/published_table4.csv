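scenario,region,newborns_idd_thousands,participation_percent,income_usd,npv_loss_usd_thousands
endpoint_2019,Africa,1740,71.8,1146,838880
endpoint_2019,Americas,272,65.1,5722,3246795
endpoint_2019,Eastern Mediterranean,636,55.1,8100,794755
endpoint_2019,Europe,559,59.3,18596,4683995
endpoint_2019,South Asia,1010,69.4,1479,433285
endpoint_2019,East Asia and Pacific,609,64.0,6372,2485492
doing_nothing,Africa,6341,70.2,1146,1326288
doing_nothing,Americas,2511,62.4,5722,14736522
doing_nothing,Eastern Mediterranean,4307,52.8,8435,3463865
doing_nothing,Europe,1748,59.3,18596,8247588
doing_nothing,South Asia,6589,68.3,1479,3092915
doing_nothing,East Asia and Pacific,3793,67.4,6372,14353332
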