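rank,area,spine_count,age_factor
1,V1,643,1
2,V2,1201,1
3,V4,2429,1
4,DP,NA,NA
5,MT,2077,1
6,8m,3200,1.30
7,5,4689,1
8,8l,3200,1.30
9,2,NA,NA
10,TEO,4812,1
11,F1,NA,NA
12,STPc,8337,1
13,7A,2572,1
14,46d,6600,1.15
15,10,6488,1.15
16,9/46v,7800,1.15
17,9/46d,7800,1.15
18,F5,NA,NA
19,TEpd,7260,1
20,PBr,NA,NA
21,7m,2294,1.30
22,LIP,2316,1
23,F2,NA,NA
24,7B,6841,1
25,ProM,NA,NA
26,STPi,8337,1
27,F7,NA,NA
28,8B,NA,NA
29,STPr,8337,1
30,24c,6825,1.15
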