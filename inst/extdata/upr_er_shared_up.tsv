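# Proteins more abundant in the VDAC-less (ΔPor-1) N. crassa strain that are
# also predicted, from transcriptome data, to be upregulated under
# ER-unfolded-protein-response-inducing conditions (DTT or tunicamycin).
# Columns: accession <TAB> description
NCU05780	glutathione S-transferase-1
NCU09519	2,5-diketo-D-gluconic acid reductase A
NCU10572	short-chain oxidoreductase
NCU01272	mitochondrial presequence protease
NCU02549	processing enhancing protein
NCU09559	clock-controlled gene-9
NCU09560	superoxide dismutase
NCU05770	catalase-2
NCU03739	ERP38 protein
NCU04930	hypothetical protein
NCU01589	heat-shock protein 60
NCU09674	O-methyltransferase family 3
NCU03611	chitin synthase-1
NCU03795	cell division control protein 12
NCU03949	nitropropane dioxygenase-1
NCU05881	DUF500 and UBA/TS-N domain-containing protein
NCU10810	mRNA-splicing protein
NCU02727	glycine cleavage system T protein
NCU06738	protein transporter sec-31
NCU01166	microcycle blastoconidiation
NCU03596	CRAL/TRIO domain-containing protein
NCU06974	histidinol-phosphatase
NCU00864	TIM-barrel enzyme family protein
NCU09223	protein disulfide-isomerase
NCU10360	hypothetical protein
NCU05495	clock-controlled gene-16
NCU01004	phosphatidylserine decarboxylase proenzyme
NCU00685	casein kinase I isoform delta
NCU00350	epoxide hydrolase
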