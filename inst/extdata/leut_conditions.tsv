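condition	n_replicas	total_ns
WT.Na.Leu	2	590
WT.Na.Ala	1	360
WT.Na.ns	3	3600
WT.Li.Leu	1	480
WT.Li.Ala	1	480
WT.Li.ns	2	2400
Y268A.Na.Leu	1	600
Y268A.Na.ns	3	4320
R5A.Na.ns	2	2640
D369A.Na.ns	3	2480
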