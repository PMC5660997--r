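accession	segment	length_nt	protein_aa
MF356208	1	3786	1237
MF356209	2	3837	1237
MF356210	3	2985	1230
MF356211	4	2628	970
MF356212	5	2243	796
MF356213	6	1616	707
MF356214	7	1856	453
MF356215	8	1267	566
MF356216	9	1096	364
MF356217	10	2339	306
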