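variant_id	cdna_change	cohort	region	exac_af	consequence	carrier_count	functional_class
Ser682Trp	2045C>G	case	US	0.00002626	missense	1	gain_of_function
Gly859Arg	2575G>A	case	NA	0.00001756	missense	1	wild_type_like
Val1442Met	4324G>A	case	US	0.00001025	missense	1	loss_of_function
Arg1463Ser	4387C>A	case	UK	0.00000832	missense	1	gain_of_function
Met1493Val	4477A>G	case	NA	NOVEL	missense	1	wild_type_like
Glu1520Lys	4558G>A	case	US	NOVEL	missense	1	loss_of_function
Intron393-1C>T	393-1C>T	control	NA	NOVEL	intronic	1	NA
Arg179Gln	536G>A	control	NA	0.00001862	missense	1	wild_type_like
Arg190Trp	568C>T	control	NA	NOVEL	missense	1	wild_type_like
Leu227Phe	679C>T	control	NA	0.00004441	missense	1	wild_type_like
Asp334Asn	1000G>A	control	NA	0.00002484	missense	1	wild_type_like
Gly863Arg	2587G>A	control	NA	0.00001581	missense	1	wild_type_like
Ala870Thr	2608G>A	control	NA	NOVEL	missense	1	wild_type_like
Met897Lys	2690T>A	control	NA	NOVEL	missense	1	wild_type_like
Val1590Ile	4768G>A	control	NA	0.000008278	missense	1	wild_type_like
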