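vent_field	sample_id	bin	snvs_per_kbp	majority_allele_freq	saav_snv_ratio	mean_coverage	total_length_bp	percent_complete	percent_redundancy
Von Damm	FS844	Bin_43	11.95	0.8027	0.2999	246.65	1918793	97.12	1.44
Von Damm	FS844	Bin_13	13.16	0.7860	0.2009	33.50	1767871	92.81	5.76
Von Damm	FS881	Bin_43	18.80	0.8005	0.2814	112.98	1943705	90.65	2.88
Von Damm	FS881	Bin_45	11.19	0.8024	0.2683	273.02	1736799	79.86	1.44
Von Damm	FS866	Bin_31	37.36	0.8147	0.2894	71.35	1835174	74.82	4.32
Piccard	FS854	Bin_99	4.00	0.7845	0.3898	2441.16	1870573	92.09	2.16
Piccard	FS856	Bin_37	4.66	0.8001	0.3600	1059.15	1934456	94.24	4.32
Piccard	FS854	Bin_7	5.06	0.6777	0.2750	18.97	1625685	90.65	5.76
Piccard	FS854	Bin_9	13.84	0.7946	0.2651	120.29	1826106	75.54	4.32
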