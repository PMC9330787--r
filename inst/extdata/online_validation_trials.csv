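trial,phase1_fp,fp_walk_time_s,phase2_fp,phase2_tp,first_command_pre_turn_s,last_command_pre_turn_s
1,1,7.00,NA,NA,NA,NA
2,0,NA,0,1,2.02,0.22
3,0,NA,0,1,2.04,0.24
4,1,2.80,NA,NA,NA,NA
5,0,NA,0,1,1.86,0.06
6,0,NA,0,1,2.36,0.56
7,0,NA,0,1,1.86,0.06
8,0,NA,0,1,1.96,0.16
9,0,NA,0,1,1.91,0.11
10,0,NA,0,1,2.11,0.31
11,0,NA,0,1,1.80,0.00
12,0,NA,0,1,1.92,0.12
13,0,NA,0,1,1.96,0.16
14,1,0.80,NA,NA,NA,NA
15,0,NA,0,1,2.15,0.35
16,0,NA,0,1,2.09,0.29
17,0,NA,0,1,2.11,0.31
18,1,0.80,NA,NA,NA,NA
19,0,NA,0,1,1.92,0.12
20,1,0.76,NA,NA,NA,NA
21,0,NA,0,1,2.07,0.27
22,1,8.00,NA,NA,NA,NA
23,0,NA,0,1,2.03,0.23
24,1,0.80,NA,NA,NA,NA
25,0,NA,0,1,1.97,0.17
26,0,NA,0,1,1.96,0.16
27,0,NA,0,1,2.03,0.23
28,1,2.80,NA,NA,NA,NA
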