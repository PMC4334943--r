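term_id	label	synonyms	parents
ENVO:00010483	environmental material
ENVO:00002006	water	liquid water	ENVO:00010483
ENVO:00002149	sea water	seawater|saline water	ENVO:00002006
ENVO:00002011	fresh water	freshwater	ENVO:00002006
ENVO:00002001	waste water	wastewater	ENVO:00002006
ENVO:00001998	soil		ENVO:00010483
ENVO:00002007	sediment		ENVO:00010483
ENVO:00002005	air		ENVO:00010483
ENVO:00002044	sludge		ENVO:00010483
ENVO:00003031	sand		ENVO:00010483
ENVO:00002982	clay		ENVO:00010483
ENVO:01000155	organic material	organic matter	ENVO:00010483
ENVO:00002042	surface water		ENVO:00002006
ENVO:01001004	groundwater	ground water	ENVO:00002006
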