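group_id,family,n_languages
00,TNG,NA
08,TNG,NA
09,TNG,11
10,TNG,18
11,TNG,NA
12,TNG,NA
15,TNG,NA
16,TNG,NA
18,TNG,NA
19,TNG,NA
20,TNG,107
21,TNG,61
22,TNG,13
23,TNG,NA
24,TNG,NA
25,TNG,5
26,TNG,3
27,TNG,6
28,TNG,NA
29,TNG,NA
31,Austronesian,1
32,Austronesian,23
33,Austronesian,NA
34,Austronesian,NA
35,Austronesian,1
36,Austronesian,NA
37,Austronesian,NA
38,Austronesian,NA
39,Austronesian,43
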