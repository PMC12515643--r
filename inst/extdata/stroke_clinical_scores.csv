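subject,sex,age,affected_side,stroke_type,fma_ue_pre,fma_ue_post,arat_pre,arat_post
1,M,59,Right,Ischemic,4,7,0,0
2,M,69,Right,Ischemic,47,49,43,47
3,F,80,Right,Ischemic,49,49,46,48
4,M,48,Right,Hemorrhagic,13,13,0,0
5,M,55,Right,Ischemic,60,60,54,54
6,M,66,Right,Ischemic,64,64,54,54
7,F,58,Right,Ischemic,8,9,0,0
8,M,64,Right,Hemorrhagic,63,63,54,54
9,M,48,Right,Hemorrhagic,8,12,0,0
10,F,58,Right,Ischemic,7,11,0,0
11,F,59,Right,Ischemic,13,13,2,2
12,M,42,Right,Hemorrhagic,32,39,26,30
13,M,68,Right,Ischemic,10,12,4,4
14,F,55,Right,Hemorrhagic,7,7,0,0
15,M,75,Right,Ischemic,54,59,54,55
16,M,60,Right,Hemorrhagic,33,38,35,39
17,M,73,Right,Ischemic,52,57,53,55
18,F,80,Right,Ischemic,36,39,36,38
19,F,73,Right,Ischemic,18,19,10,10
20,M,72,Right,Ischemic,52,53,55,55
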