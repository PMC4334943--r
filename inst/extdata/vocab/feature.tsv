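term_id	label	synonyms	parents
ENVO:00002297	environmental feature
ENVO:00000091	beach		ENVO:00002297
ENVO:00000150	coral reef	reef	ENVO:00002297
ENVO:00000045	estuary		ENVO:00002297
ENVO:00000020	lake		ENVO:00002297
ENVO:00000022	river	stream	ENVO:00002297
ENVO:00000016	sea	ocean	ENVO:00002297
ENVO:00000081	mountain		ENVO:00002297
ENVO:00000133	glacier		ENVO:00002297
ENVO:00000051	hot spring	thermal spring	ENVO:00002297
ENVO:00000215	hydrothermal vent		ENVO:00002297
ENVO:00000043	wetland	marsh	ENVO:00002297
ENVO:00000114	agricultural field	cropland	ENVO:00002297
ENVO:00000292	watershed		ENVO:00002297
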