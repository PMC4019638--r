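review_id,trial_id,outcome_label
R1,T01,pain
R1,T02,pain
R1,T03,pain
R1,T04,pain
R1,T05,pain
R2,T06,function
R2,T07,function
R2,T08,function
R2,T09,function
R2,T10,function
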