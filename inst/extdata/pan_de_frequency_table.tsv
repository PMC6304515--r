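item_id	BLCA	BRCA	HNSC	KICH	KIRC	KIRP	LIHC	LUAD	LUSC	STAD	THCA	frequency
ADGRB3	down	down	down	down	down	down	down	down	down	down	up	11
ASF1B	up	up	up	up	up	up	up	up	up	up	up	11
CDKN2A	up	up	up	up	up	up	up	up	up	up	up	11
CDT1	up	up	up	up	up	up	up	up	up	up	up	11
DPT	down	down	down	down	down	down	down	down	down	down	down	11
E2F1	up	up	up	up	up	up	up	up	up	up	up	11
E2F7	up	up	up	up	up	up	up	up	up	up	up	11
MYBL2	up	up	up	up	up	up	up	up	up	up	down	11
TCEAL2	down	down	down	down	down	down	down	down	down	down	down	11
TGFBR3	down	down	down	down	down	down	down	down	down	down	down	11
miR-183	up	up	up	up	/	up	up	up	up	up	up	10
miR-96	up	up	up	up	/	up	up	up	up	up	up	10
miR-1	down	down	down	down	down	down	/	down	down	down	/	9
miR-1258	down	down	down	up	/	/	down	down	down	down	down	9
miR-133a	down	down	down	down	down	down	/	down	down	down	/	9
miR-135b	up	up	up	down	/	up	up	up	up	up	/	9
miR-144	/	down	down	up	up	up	/	down	down	down	down	9
miR-182	up	up	/	up	/	up	up	up	up	up	up	9
miR-195	down	down	down	down	/	down	down	down	down	down	/	9
miR-21	up	up	up	/	up	up	up	up	/	up	up	9
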