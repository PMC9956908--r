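aethiops_1	2621677
aethiops_Z	2300297
aethiops_2	1355952
aethiops_3	1149221
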