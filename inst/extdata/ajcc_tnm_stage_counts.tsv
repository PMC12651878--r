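combination	stage	n
T1N0M0	I	1254
T2N0M0	II	745
T3N0M0	II	252
T4N0M0	III	25
T1N1M0	III	56
T2N1M0	III	142
T3N1M0	III	233
T4N1M0	III	21
T1N0M1	IV	22
T2N0M1	IV	150
T3N0M1	IV	86
T4N0M1	IV	35
T1N1M1	IV	15
T2N1M1	IV	81
T3N1M1	IV	131
T4N1M1	IV	30
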