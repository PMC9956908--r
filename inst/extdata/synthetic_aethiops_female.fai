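chr_neoZ	27200000	0	80	81
chr_1	26100000	0	80	81
chr_2	25400000	0	80	81
chr_3	24900000	0	80	81
chr_4	24300000	0	80	81
chr_5	23800000	0	80	81
chr_6	23100000	0	80	81
chr_7	22600000	0	80	81
chr_8	22000000	0	80	81
chr_9	21500000	0	80	81
chr_10	20700000	0	80	81
chr_11	19900000	0	80	81
chr_12	19100000	0	80	81
chr_13	18400000	0	80	81
chr_14	17600000	0	80	81
chr_15	16200000	0	80	81
chr_16	14800000	0	80	81
chr_17	13200000	0	80	81
chr_18	11400000	0	80	81
chr_W	2266000	0	80	81
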