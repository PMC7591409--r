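exposure_age,outcome_age,outcome,group,events,pct,n_total
75,80,any_fall,faller_frail,27,54.0,631
75,80,any_fall,faller_nonfrail,53,47.3,631
75,80,any_fall,nonfaller_frail,22,37.3,631
75,80,any_fall,nonfaller_nonfrail,100,24.4,631
75,80,recurrent,faller_frail,18,36.0,625
75,80,recurrent,faller_nonfrail,39,35.5,625
75,80,recurrent,nonfaller_frail,16,27.6,625
75,80,recurrent,nonfaller_nonfrail,45,11.1,625
80,85,any_fall,faller_frail,30,76.9,358
80,85,any_fall,faller_nonfrail,43,57.3,358
80,85,any_fall,nonfaller_frail,31,48.4,358
80,85,any_fall,nonfaller_nonfrail,67,37.2,358
80,85,recurrent,faller_frail,20,57.1,347
80,85,recurrent,faller_nonfrail,23,32.4,347
80,85,recurrent,nonfaller_frail,18,28.1,347
80,85,recurrent,nonfaller_nonfrail,33,18.6,347
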