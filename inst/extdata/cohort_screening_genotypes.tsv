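sample_id	phenotype	IQCB1=wt/delCT
205	Normal (parent of affected)	wt/delCT
208	Normal (parent of affected)	wt/delCT
222	Normal	wt/wt
223	Normal	wt/wt
228	Normal (sibling of affected)	wt/delCT
229	Normal	wt/wt
230	Normal	wt/wt
233	Normal	wt/wt
234	Normal	wt/wt
235	PRA-affected (proband)	delCT/delCT
236	Normal (sibling of affected)	wt/wt
240	Normal	wt/delCT
247	PRA-affected	delCT/delCT
248	Normal (sibling of affected)	wt/delCT
251	Normal	wt/wt
258	Normal	wt/delCT
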