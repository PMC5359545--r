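sample_id	phenotype	IQCB1=wt/delCT	CHD3=A/G	CNGB1=C/T	DTHD1_942=C/G	RBP3=G/A	USH1C=C/T	CDH23=C/T	DTHD1_144=A/C
247	PRA-affected	delCT/delCT	GG	TT	GG	AA	TT	TT	CC
205	Normal	wt/delCT	AG	CT	GC	AG	CT	CT	CA
208	Normal	wt/delCT	AG	CT	GC	AG	CT	CT	CA
235	PRA-affected	delCT/delCT	AA	CC	GG	AG	CT	TT	CC
240	Normal	wt/delCT	AA	CT	GG	GG	CT	CT	CA
248	Normal	wt/delCT	/	CC	/	AG	TT	CC	/
258	Normal	wt/delCT	AA	TT	GC	GG	CC	CC	AA
236	Normal	wt/wt	AA	CC	GC	AG	CT	CT	CA
230	Normal	wt/wt	AA	CC	CC	GG	CC	CC	AA
234	Normal	wt/wt	/	/	CC	GG	/	/	AA
251	Normal	wt/wt	AA	CC	CC	GG	CC	CT	AA
229	Normal	wt	AA	CC	CC	GG	CT	CC	AA
222	Normal	wt	AA	CT	CC	GG	TT	CT	AA
233	Normal	wt	AA	CC	CC	GG	TT	CC	CA
223	Normal	wt	AA	CC	GC	GG	CT	CC	CA
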