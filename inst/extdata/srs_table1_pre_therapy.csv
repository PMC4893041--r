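patient_id,age,sex,joints_n,joints_global,glands_n,glands_global
1,18,F,13,23,4,6
2,25,F,4,18,1,2
3,40,F,5,5,2,2
4,32,F,2,2,2,2
5,45,F,1,3,1,1
6,60,F,7,13,0,0
7,22,M,10,15,0,0
8,36,F,4,8,2,4
9,29,F,4,14,0,0
10,42,F,8,14,2,6
11,40,F,10,14,0,0
12,52,F,10,20,0,0
13,54,M,10,24,1,3
14,60,F,12,22,0,0
15,62,F,8,16,2,2
16,64,F,17,29,1,2
17,39,F,20,52,2,1
18,70,F,8,14,2,4
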