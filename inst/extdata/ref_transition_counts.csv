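period,from_state,NC,IN,DI
1,ALL,21946,1923,1188
2,NC,19688,1480,778
2,IN,1481,101,341
2,DI,833,324,31
3,NC,19860,1356,786
3,IN,1433,88,384
3,DI,811,309,30
4,NC,20003,1247,854
4,IN,1322,70,361
4,DI,860,310,30
5,NC,19645,1345,1195
5,IN,1191,64,372
5,DI,874,320,51
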