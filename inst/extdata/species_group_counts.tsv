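mosquito_taxon	n_specimens	pct_specimens	birds	non_human_mammals	humans	n_host_species	aggregate_taxon
Aedes albopictus	1	0.1	0	0	1	1	FALSE
Aedes cinereus	25	3.2	2	19	4	9	FALSE
Aedes rossicus	42	5.4	0	37	5	5	FALSE
Aedes vexans	363	46.8	4	325	34	21	FALSE
Aedes/Ochlerotatus spp.	15	1.9	0	14	1	4	TRUE
Anopheles claviger	11	1.4	0	7	4	5	FALSE
Anopheles maculipennis (s.l.)	10	1.3	1	9	0	6	FALSE
Anopheles plumbeus	1	0.1	0	0	1	1	FALSE
Coquillettidia richiardii	11	1.4	0	10	1	5	FALSE
Culiseta annulata	18	2.3	0	14	4	5	FALSE
Culiseta morsitans	18	2.3	2	5	11	4	FALSE
Culex pipiens pipiens form pipiens	100	12.9	28	37	35	15	FALSE
Culex pipiens (s.l.)/torrentium	10	1.3	4	0	6	2	TRUE
Culex spp.	1	0.1	1	0	0	1	TRUE
Culex torrentium	15	1.9	8	1	6	3	FALSE
Ochlerotatus annulipes	8	1.0	0	3	5	3	FALSE
Ochlerotatus cantans	99	12.8	0	73	26	5	FALSE
Ochlerotatus cantans/annulipes	2	0.3	0	1	1	2	TRUE
Ochlerotatus communis	3	0.4	0	2	1	2	FALSE
Ochlerotatus excrucians	1	0.1	0	0	1	1	FALSE
Ochlerotatus geniculatus	2	0.3	0	0	2	1	FALSE
Ochlerotatus refiki	1	0.1	0	0	1	1	FALSE
Ochlerotatus rusticus	2	0.3	0	2	0	2	FALSE
Ochlerotatus sticticus	16	2.1	1	13	2	7	FALSE
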