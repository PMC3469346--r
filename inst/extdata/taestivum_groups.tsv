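group	locus	n_transcripts
6	Gli-A1	140
7	Gli-A1	38
3	Gli-B1	41
5	Gli-B1	125
8	Gli-B1	19
9	Gli-D1	293
10	Gli-D1	61
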