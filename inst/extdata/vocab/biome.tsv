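term_id	label	synonyms	parents
ENVO:00000428	biome
ENVO:00002030	aquatic biome		ENVO:00000428
ENVO:00000447	marine biome	sea biome	ENVO:00002030
ENVO:00000873	freshwater biome		ENVO:00002030
ENVO:00000446	terrestrial biome		ENVO:00000428
ENVO:01000174	forest biome	woodland biome	ENVO:00000446
ENVO:01000177	grassland biome	prairie biome|steppe biome	ENVO:00000446
ENVO:01000179	desert biome		ENVO:00000446
ENVO:01000180	tundra biome		ENVO:00000446
ENVO:01000252	freshwater lake biome	lake biome	ENVO:00000873
ENVO:01000253	freshwater river biome	river biome	ENVO:00000873
ENVO:01000048	coastal water biome	coastal biome	ENVO:00000447
ENVO:01000049	marine benthic biome		ENVO:00000447
ENVO:01000023	marine pelagic biome		ENVO:00000447
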