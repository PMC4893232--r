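mosquito_taxon	host_group	period	n_specimens	pct_within_species_period
Aedes vexans	bird	early	1	1.5
Aedes vexans	human	early	1	1.5
Aedes vexans	non-human mammal	early	63	96.9
Aedes vexans	bird	late	3	1.0
Aedes vexans	human	late	33	11.1
Aedes vexans	non-human mammal	late	262	87.9
Culex pipiens pipiens form pipiens	bird	early	3	21.4
Culex pipiens pipiens form pipiens	human	early	5	35.7
Culex pipiens pipiens form pipiens	non-human mammal	early	6	42.9
Culex pipiens pipiens form pipiens	bird	late	25	29.1
Culex pipiens pipiens form pipiens	human	late	30	34.9
Culex pipiens pipiens form pipiens	non-human mammal	late	31	36.0
Ochlerotatus cantans	bird	early	0	0
Ochlerotatus cantans	human	early	19	27.1
Ochlerotatus cantans	non-human mammal	early	51	72.9
Ochlerotatus cantans	bird	late	0	0
Ochlerotatus cantans	human	late	7	24.1
Ochlerotatus cantans	non-human mammal	late	22	75.9
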