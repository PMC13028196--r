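category,subtype,count
IN,Mono—Addition of SU,3818
IN,Comb—Addition of insulin,2022
IN,Comb—Addition of SU,951
IN,Mono—Addition of insulin,804
IN,Comb—Switching from non-SU to insulin,470
IN,Comb—Switching from SU to insulin,450
IN,Mono—Switching from non-SU to SU,252
IN,Comb—Switching from non-SU to SU,91
IN,Mono—Switching from non-SU to insulin,79
DI,Comb—Discontinuation of SU,3148
DI,Comb—Discontinuation of insulin,1974
DI,Mono—Discontinuation of SU,311
DI,Comb—Switching from SU to non-SU,264
DI,Comb—Switching from insulin to non-SU,259
DI,Mono—Discontinuation of insulin,214
DI,Comb—Switching from insulin to SU,101
DI,Mono—Switching from SU to non-SU,95
DI,Mono—Switching from insulin to non-SU,22
DI,Mono—Switching from insulin to SU,13
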