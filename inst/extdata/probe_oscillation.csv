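trial,action,reward,phase
1,R,0,forced
2,R,0,forced
3,R,0,forced
4,R,0,forced
5,R,0,forced
6,R,0,forced
7,L,0,forced
8,R,0,forced
9,L,0,forced
10,NA,NA,on
11,NA,NA,on
12,NA,NA,on
13,NA,NA,on
14,NA,NA,on
15,NA,NA,on
16,NA,NA,on
17,NA,NA,on
18,NA,NA,on
19,NA,NA,on
20,NA,NA,on
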