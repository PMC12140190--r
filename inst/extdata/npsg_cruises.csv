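cruise,official_id,direction,season,start_date,end_date,duration_days,distance_km
NSP1,KOK1606,north,spring,2016-04-20,2016-05-04,15,3648
NSP2,MGL1704,north,spring,2017-05-26,2017-06-13,19,4566
NSU1,KM1712,north,summer,2017-07-31,2017-08-30,31,5504
NSU2,KM1713,north,summer,2017-09-05,2017-09-26,22,3634
NSP3,KM1906,north,spring,2019-04-10,2019-04-29,20,6263
SFA1,KM1923,south,fall,2019-12-06,2019-12-16,11,3760
EFA1/SFA2/SFA3,TN397,east/south,fall,2021-11-18,2021-12-15,28,7654
EWI1,TN398,east,winter,2021-12-18,2021-12-30,13,4503
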