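item_id	BLCA	BRCA	HNSC	KICH	KIRC	KIRP	LIHC	LUAD	LUSC	STAD	THCA	frequency
miR-183/NEGR1	0.64	0.50	/	0.31	/	0.18	/	/	/	0.50	0.25	6
miR-210/SCN7A	0.16	-0.37	0.20	/	0.31	0.49	/	/	/	0.00	/	6
miR-21/EPM2A	/	0.34	0.65	/	0.23	0.30	0.03	/	/	0.49	/	6
miR-21/LIFR	0.42	0.47	0.62	/	/	0.32	/	/	/	/	-0.05	5
miR-182/PCOLCE2	0.51	0.30	/	0.68	/	0.42	/	/	/	0.30	/	5
miR-21/FAXDC2	/	0.57	0.74	/	/	/	0.04	/	/	0.47	-0.32	5
miR-21/SOX5	0.16	0.66	/	/	/	/	/	/	/	0.24	0.43	4
miR-183/AKAP12	0.40	0.43	/	/	/	/	/	/	/	0.77	0.05	4
miR-195/CCNE1	0.16	-0.13	0.08	/	/	/	/	0.25	/	/	/	4
miR-96/RECK	0.63	0.23	0.45	/	/	/	/	/	/	0.19	/	4
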