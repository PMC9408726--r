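year,month,region,hw_days,ed_visits
2011,May,Coastal,3,65
2011,May,Piedmont,1,37
2011,June,Coastal,21,309
2011,June,Piedmont,14,334
2011,July,Coastal,22,225
2011,July,Piedmont,25,417
2011,August,Coastal,10,195
2011,August,Piedmont,15,302
2011,September,Coastal,0,0
2011,September,Piedmont,0,0
2012,May,Coastal,0,0
2012,May,Piedmont,0,0
2012,June,Coastal,5,45
2012,June,Piedmont,6,95
2012,July,Coastal,23,306
2012,July,Piedmont,27,520
2012,August,Coastal,0,0
2012,August,Piedmont,8,112
2012,September,Coastal,2,35
2012,September,Piedmont,6,52
2014,May,Coastal,0,0
2014,May,Piedmont,0,0
2014,June,Coastal,6,101
2014,June,Piedmont,7,141
2014,July,Coastal,7,103
2014,July,Piedmont,11,149
2014,August,Coastal,0,0
2014,August,Piedmont,5,55
2014,September,Coastal,5,68
2014,September,Piedmont,6,92
2015,May,Coastal,0,0
2015,May,Piedmont,0,0
2015,June,Coastal,15,817
2015,June,Piedmont,16,897
2015,July,Coastal,14,306
2015,July,Piedmont,19,569
2015,August,Coastal,5,117
2015,August,Piedmont,9,177
2015,September,Coastal,2,25
2015,September,Piedmont,3,54
2016,May,Coastal,0,0
2016,May,Piedmont,0,0
2016,June,Coastal,5,80
2016,June,Piedmont,8,204
2016,July,Coastal,24,721
2016,July,Piedmont,26,950
2016,August,Coastal,19,366
2016,August,Piedmont,24,499
2016,September,Coastal,2,30
2016,September,Piedmont,5,106
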