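name	first	last	region
NT	1	9	terminus
TM1i	10	19	i
TM1m	20	27	m
TM1e	28	37	e
EL1	38	40	loop
TM2e	41	46	e
TM2m	47	56	m
TM2i	57	70	i
IL1	71	87	loop
TM3i	88	103	i
TM3m	104	108	m
TM3e	109	124	e
EL2	125	165	loop
TM4e	166	174	e
TM4i	175	183	i
IL2	184	190	loop
TM5i	191	200	i
TM5e	201	213	e
EL3	214	240	loop
TM6e	241	249	e
TM6m	250	261	m
TM6i	262	268	i
IL3	269	275	loop
TM7i	276	285	i
TM7m	286	292	m
TM7e	293	306	e
EL4a	307	319	loop
EL4b	320	336	loop
TM8e	337	350	e
TM8m	351	359	m
TM8i	360	369	i
IL4	370	374	loop
TM9i	375	384	i
TM9e	385	395	e
EL5	396	398	loop
TM10e	399	406	e
TM10m	407	411	m
TM10i	412	424	i
IL5	425	446	loop
TM11i	447	469	i
TM11e	470	477	e
EL6	478	482	loop
TM12e	483	492	e
TM12i	493	515	i
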