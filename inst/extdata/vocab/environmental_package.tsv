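term_id	label	synonyms	parents
PKG:0000001	water
PKG:0000002	soil
PKG:0000003	air
PKG:0000004	sediment
PKG:0000005	host-associated
PKG:0000006	human-gut	human gut
PKG:0000007	plant-associated
PKG:0000008	wastewater-sludge	wastewater/sludge
PKG:0000009	built environment
PKG:0000010	microbial mat-biofilm	microbial mat/biofilm
PKG:0000011	miscellaneous natural or artificial environment	misc environment
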