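symbol	entrez_name	fc_ipsi	fc_contra	ratio	compartment	molecule_type
CSF1	colony stimulating factor 1 (macrophage)	3.70	2.09	1.77	extracellular space	cytokine
SPP1	secreted phosphoprotein 1	37.91	2.37	15.99	extracellular space	cytokine
ERAP1	endoplasmic reticulum aminopeptidase 1	5.84	3.05	1.92	extracellular space	peptidase
LCN2	lipocalin 2	71.82	3.90	18.44	extracellular space	transporter
TGFB2	transforming growth factor, beta 2	-4.00	-7.97	1.99	extracellular space	growth factor
SERPINA3	serpin peptidase inhibitor, clade A (alpha-1 antiproteinase, antitrypsin), member 3	58.49	2.51	23.31	extracellular space	other
SERPING1	serpin peptidase inhibitor, clade G (C1 inhibitor), member 1	5.81	2.03	2.86	extracellular space	other
TIMP1	TIMP metallopeptidase inhibitor 1	38.49	2.10	18.32	extracellular space	other
HLA-C	major histocompatibility complex, class I, C	9.30	3.66	2.54	plasma membrane	transmembrane receptor
IGSF6	immunoglobulin superfamily, member 6	22.46	3.27	6.87	plasma membrane	transmembrane receptor
IL13RA1	interleukin 13 receptor, alpha 1	4.53	2.27	1.99	plasma membrane	transmembrane receptor
IL6ST	interleukin 6 signal transducer (gp130, oncostatin M receptor)	2.31	-3.28	7.57	plasma membrane	transmembrane receptor
THBD	thrombomodulin	3.85	2.09	1.84	plasma membrane	transmembrane receptor
KCNN4	potassium intermediate/small conductance calcium-activated channel, subfamily N, member 4	3.09	-9.43	29.12	plasma membrane	ion channel
EGFR	epidermal growth factor receptor	6.77	2.37	2.85	plasma membrane	kinase
MGLL	monoglyceride lipase	-7.85	-18.15	2.31	plasma membrane	enzyme
CD44	CD44 molecule (Indian blood group)	15.56	2.40	6.49	plasma membrane	other
CLEC12A	C-type lectin domain family 12, member A	10.92	2.15	5.08	plasma membrane	other
ITGA5	integrin, alpha 5 (fibronectin receptor, alpha polypeptide)	4.83	2.68	1.80	plasma membrane	other
SDC1	syndecan 1	13.68	2.57	5.33	plasma membrane	other
LYN	v-yes-1 Yamaguchi sarcoma viral related oncogene homolog	6.94	3.78	1.84	cytoplasm	kinase
PDE4B	phosphodiesterase 4B, cAMP-specific	5.60	2.36	2.37	cytoplasm	enzyme
PTPN4	protein tyrosine phosphatase, non-receptor type 4 (megakaryocyte)	4.49	2.21	2.03	cytoplasm	phosphatase
RASA1	RAS p21 protein activator (GTPase activating protein) 1	2.39	-2.11	5.04	cytoplasm	transporter
HSPB1	heat shock 27 kDa protein 1	46.92	2.64	17.78	cytoplasm	other
LCP1	lymphocyte cytosolic protein 1 (L-plastin)	6.08	2.80	2.17	cytoplasm	other
LSP1	lymphocyte-specific protein 1	11.72	2.14	5.47	cytoplasm	other
MYO1F	myosin IF	4.27	2.26	1.89	cytoplasm	other
CBL	Cas-Br-M (murine) ecotropic retroviral transforming sequence	-3.40	-6.13	1.80	nucleus	transcription regulator
CEBPD	CCAAT/enhancer binding protein (C/EBP), delta	11.27	2.04	5.53	nucleus	transcription regulator
DEK	DEK oncogene	-3.01	-7.35	2.45	nucleus	transcription regulator
STAT3	signal transducer and activator of transcription 3 (acute-phase response factor)	4.22	-3.77	15.91	nucleus	transcription regulator
MX1	myxovirus (influenza virus) resistance 1, interferon-inducible protein p78 (mouse)	28.18	7.33	3.85	nucleus	enzyme
TOP2A	topoisomerase (DNA) II alpha 170 kDa	2.26	-2.41	5.44	nucleus	enzyme
THRA	thyroid hormone receptor, alpha	-2.80	-11.52	4.12	nucleus	ligand-dependent nuclear receptor
CCND1	cyclin D1	2.15	-2.03	4.36	nucleus	other
Slpi (includes others)	secretory leukocyte peptidase inhibitor	82.91	3.12	26.58	unknown	other
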