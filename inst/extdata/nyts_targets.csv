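year,product,prev,ciLow,ciHigh
2011,CC,15.8,14.0,17.7
2012,CC,14.0,12.1,16.1
2013,CC,12.7,10.8,14.9
2014,CC,9.2,7.9,10.8
2011,EC,1.5,1.2,1.9
2012,EC,2.8,2.3,3.5
2013,EC,4.5,3.7,5.5
2014,EC,13.4,11.9,15.1
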