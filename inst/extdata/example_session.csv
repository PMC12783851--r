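step,pile_id,reward_count
1,1,0
2,2,0
3,4,0
4,17,0
5,16,0
6,40,0
7,39,0
8,25,0
9,36,0
10,49,0
11,48,0
12,60,0
13,72,0
14,61,0
15,62,0
16,37,0
17,38,0
18,26,0
19,14,0
20,13,0
21,12,0
22,24,0
23,0,0
24,3,0
25,27,0
26,42,0
27,54,0
28,41,0
29,52,0
30,77,0
31,65,0
32,76,0
33,99,0
34,87,0
35,86,0
36,98,0
37,73,0
38,50,0
39,51,0
40,53,0
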