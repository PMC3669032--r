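function_name	unique_genes	overlap_ir	percent
Cellular movement	381	209	55
Cellular growth and proliferation	583	227	39
Cancer	663	225	34
Cellular development	499	208	42
Cell death	472	202	43
Neurological disease	663	185	28
Genetic disorder	1023	267	26
Gene expression	441	151	34
Skeletal and muscular disorders	538	191	36
Tissue development	479	203	42
Cell cycle	296	111	38
Cell morphology	267	133	50
Immune cell trafficking	231	216	94
Dermatological diseases & conditions	268	147	55
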