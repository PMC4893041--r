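patient_id,pre_n,pre_global,pre_functional,post_n,post_global,post_functional
1,4,6,7.5,3,3,7.5
3,2,2,5.0,2,2,5.2
4,2,2,4.5,2,2,4.4
5,1,1,5.4,1,1,6.3
6,0,0,6.2,0,0,6.1
7,0,0,5.2,0,0,6.1
8,2,4,5.7,2,2,6.5
9,0,0,6.5,0,0,6.7
12,0,0,7.6,0,0,7.4
14,0,0,6.2,0,0,6.4
18,2,4,5.8,2,3,5.9
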