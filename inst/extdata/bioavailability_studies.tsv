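drug	f_auc	f_auc_sd	f_urine	f_urine_sd	dose_over_auc_oral	cl_after_oral_printed	cl_iv	cl_gut_printed	ratio_printed	computable	source_ref	note
Sodium fluoride	1.233	0.308	0.886	0.191	9.81	8.68	10.8	44.3	4.1	TRUE	R18	10 paired measurements in 6 subjects
Cimetidine	1.119	0.399	0.595	0.156	50.4	30.0	48.5	78.6	1.6	TRUE	R21	16 paired measurements in 9 subjects
Indoprofen (capsule)	1.018	0.353	0.891	0.261	3.48	3.10	3.47	29.1	8.4	TRUE	R31	100 mg capsule; 4 paired measurements
Letrozole	0.991	NA	0.937	NA	2.04	1.91	2.21	14.1	6.4	TRUE	R32	NA
Allopurinol	0.904	NA	0.814	NA	50.7	41.3	46.6	363	7.8	TRUE	R33	NA
Indoprofen (tablet)	0.867	0.146	0.867	NA	3.39	2.94	2.97	291	98	TRUE	R31	200 mg tablet; urinary F as used in the published clearance table differs from the 0.809 urinary ratio of the bioavailability comparison
Hydroxychloroquine	0.79	0.12	0.69	0.15	63.9	44.1	50.0	374	7.5	TRUE	R34	NA
Cilazapril (measured as cilazaprilat)	0.775	0.101	0.571	0.103	NA	NA	NA	NA	NA	FALSE	R35	bioavailability comparison truncated at 24 h; extrapolated areas unavailable
Mesna	0.680	0.413	0.58	0.173	123	71.5	77.9	870	11	TRUE	R36	NA
Ranitidine	0.52	0.11	0.38	NA	84.7	32.2	44.6	116	2.6	TRUE	R37	NA
Cilazaprilat	0.290	0.148	0.186	0.099	NA	NA	NA	NA	NA	FALSE	R35	bioavailability comparison truncated at 24 h; extrapolated areas unavailable
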