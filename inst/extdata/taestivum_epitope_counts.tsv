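epitope	6	7	3	5	8	9	10	printed_sum
DQ2-gamma-VIIb	701	144	72	230	57	1257	50	2511
DQ2-gamma-VI	224	0	0	0	38	678	50	990
DQ2-glia-gamma2a	140	30	36	59	38	684	0	987
DQ2-gamma-II	136	0	41	125	0	293	61	656
DQ2-gamma-I	120	38	41	115	19	293	61	567
DQ2-gamma-VIIa	0	0	0	115	19	0	0	134
DQ2-gamma-IV	0	0	0	0	0	0	61	61
DQ2-gamma-III	0	0	0	0	0	0	50	50
DQ2-glia-gamma2b	0	0	0	0	0	0	50	50
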