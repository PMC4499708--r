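lineage	species	genome_size_mb	n_predicted_genes	n_family_genes
Algae	Chlamydomonas reinhardtii	120.41	14488	1
Moss	Physcomitrella patens	477.95	35936	28
Lycophytes	Selaginella moellendorffii	212.5	34782	20
Dicots	Arabidopsis thaliana	119.67	33583	38
Dicots	Populus trichocarpa	485.67	42577	77
Dicots	Vitis vinifera	486.26	28268	41
Dicots	Solanum lycopersicum	781.51	27466	49
Dicots	Glycine max	973.49	50202	89
Monocots	Oryza sativa	382.78	30534	62
Monocots	Zea mays	2065.7	39454	60
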