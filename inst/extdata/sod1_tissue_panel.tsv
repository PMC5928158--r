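tissue	mean_trisomic	mean_euploid	published_ratio
brain	1807	1236	1.46
LCL	1762	1259	1.40
blood	1467	1138	1.29
fibroblast	2937	1845	1.59
thymus	751	488	1.54
iPSC	1774	1701	1.04
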