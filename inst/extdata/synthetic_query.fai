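ligea_Z	1400000
ligea_1	1355952
ligea_2	1340364
ligea_3	1281313
ligea_4	1149221
ligea_5	900297
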