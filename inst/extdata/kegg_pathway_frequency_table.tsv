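term_id	term_name	cancers	frequency
hsa04110	Cell cycle	BLCA;BRCA;HNSC;KIRC;KIRP;LUAD;LUSC;STAD	8
hsa05200	Pathways in cancer	BLCA;BRCA;KIRP;LUAD;STAD;THCA	6
hsa00071	Fatty acid degradation	HNSC;KIRC;KIRP;LIHC	4
hsa04020	Calcium signaling pathway	BLCA;KIRP;LIHC;STAD	4
hsa04114	Oocyte meiosis	BLCA;BRCA;HNSC;KIRP	4
hsa04115	p53 signaling pathway	BRCA;HNSC;LUSC;STAD	4
hsa04510	Focal adhesion	BLCA;BRCA;KIRC;LUAD	4
hsa05205	Proteoglycans in cancer	BLCA;BRCA;KIRC;LIHC	4
hsa05414	Dilated cardiomyopathy	BLCA;BRCA;HNSC;KICH	4
hsa04024	cAMP signaling pathway	BLCA;KICH;STAD	3
hsa04068	FoxO signaling pathway	BLCA;BRCA;KIRP	3
hsa04151	PI3K-Akt signaling pathway	BLCA;KIRC;LUAD	3
hsa04512	ECM-receptor interaction	BLCA;LUAD;LUSC	3
hsa04550	Signaling pathways regulating pluripotency of stem cells	BLCA;BRCA;LIHC	3
hsa04914	Progesterone-mediated oocyte maturation	BLCA;BRCA;HNSC	3
hsa05161	Hepatitis B	BLCA;KIRC;STAD	3
hsa05202	Transcriptional misregulation in cancer	HNSC;KIRC;STAD	3
hsa05410	Hypertrophic cardiomyopathy (HCM)	BLCA;BRCA;HNSC	3
hsa05166	HTLV-I infection	BRCA;KIRC;LUSC	3
hsa04931	Insulin resistance	BLCA;BRCA;KIRP	3
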