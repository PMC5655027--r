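sample_id	year	vent_field	reads_in_metagenome	shannon_16s	shannon_bins
FS841	2012	Von Damm	53842644	189.83	NA
FS842	2012	Von Damm	64300743	175.35	0.64
FS844	2012	Von Damm	103787346	145.76	2.05
FS848	2012	Von Damm	77333359	105.03	0.693
FS849	2012	Von Damm	26061468	186.84	NA
FS851	2012	Piccard	75912423	140.51	NA
FS852	2012	Piccard	37753638	63.08	NA
FS854	2012	Piccard	140664299	91.66	1.97
FS856	2012	Piccard	104123722	78.42	1.79
FS866	2013	Von Damm	24088594	168.83	1.73
FS872	2013	Von Damm	40397883	159.81	NA
FS874	2013	Von Damm	65834175	45.36	1.10
FS877	2013	Von Damm	152063932	107.02	1.10
FS879	2013	Von Damm	24723930	80.57	1.04
FS881	2013	Von Damm	167339253	163.11	1.93
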