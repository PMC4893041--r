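patient_id,pre_n,pre_global,pre_severity,post_n,post_global,post_severity
1,13,23,1.8,6,8,1.3
3,5,5,1.0,4,4,1.0
4,2,2,1.0,2,2,1.0
5,1,3,3.0,1,1,1.0
6,7,13,1.9,3,4,1.3
7,10,15,1.5,6,7,1.2
8,4,8,2.0,3,4,1.3
9,4,14,3.5,2,5,2.5
12,10,20,2.0,7,13,1.9
14,12,22,1.8,5,6,1.2
18,8,14,1.8,2,3,1.5
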