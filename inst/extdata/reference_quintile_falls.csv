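exposure_age,outcome_age,quintile,none,one,two,three_plus
75,75,1,167,14,5,0
75,75,2,145,19,12,6
75,75,3,134,27,12,8
75,75,4,117,30,13,17
75,75,5,91,36,23,38
75,80,1,111,11,10,8
75,80,2,105,17,11,9
75,80,3,95,28,12,5
75,80,4,96,18,14,13
75,80,5,78,20,20,22
75,85,1,50,13,9,3
75,85,2,45,15,8,6
75,85,3,41,17,10,5
75,85,4,31,17,11,15
75,85,5,38,6,11,20
80,85,1,47,9,8,5
80,85,2,38,16,10,6
80,85,3,40,13,11,5
80,85,4,32,18,9,11
80,85,5,30,10,10,19
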