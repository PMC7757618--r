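scenario,region,births_thousands,tgr_percent,newborns_idd_thousands
endpoint_2019,Africa,33681,4.8,1740
endpoint_2019,Americas,15074,1.7,272
endpoint_2019,Eastern Mediterranean,15406,3.9,636
endpoint_2019,Europe,11119,5.1,559
endpoint_2019,South Asia,36518,2.8,1010
endpoint_2019,East Asia and Pacific,24350,3.1,609
doing_nothing,Africa,38898,15.6,6341
doing_nothing,Americas,20181,11.0,2511
doing_nothing,Eastern Mediterranean,17773,24.2,4307
doing_nothing,Europe,10445,12.8,1748
doing_nothing,South Asia,53128,13.0,6589
doing_nothing,East Asia and Pacific,33538,10.5,3793
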