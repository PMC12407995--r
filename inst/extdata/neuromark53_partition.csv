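component_id,network,label
1,SC,SC_1
2,SC,SC_2
3,SC,SC_3
4,SC,SC_4
5,SC,SC_5
6,AUD,AUD_1
7,AUD,AUD_2
8,SM,SM_1
9,SM,SM_2
10,SM,SM_3
11,SM,SM_4
12,SM,SM_5
13,SM,SM_6
14,SM,SM_7
15,SM,SM_8
16,SM,SM_9
17,VIS,VIS_1
18,VIS,VIS_2
19,VIS,VIS_3
20,VIS,VIS_4
21,VIS,VIS_5
22,VIS,VIS_6
23,VIS,VIS_7
24,VIS,VIS_8
25,VIS,VIS_9
26,CC,CC_1
27,CC,CC_2
28,CC,CC_3
29,CC,CC_4
30,CC,CC_5
31,CC,CC_6
32,CC,CC_7
33,CC,CC_8
34,CC,CC_9
35,CC,CC_10
36,CC,CC_11
37,CC,CC_12
38,CC,CC_13
39,CC,CC_14
40,CC,CC_15
41,CC,CC_16
42,CC,CC_17
43,DM,DM_1
44,DM,DM_2
45,DM,DM_3
46,DM,DM_4
47,DM,DM_5
48,DM,DM_6
49,DM,DM_7
50,CB,CB_1
51,CB,CB_2
52,CB,CB_3
53,CB,CB_4
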