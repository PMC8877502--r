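# Proteins more abundant in the VDAC-less (ΔPor-1) N. crassa strain that are
# also more abundant in menadione-treated, oxidatively stressed cells
# (transcriptome-derived oxidative-stress signature).
# Columns: accession <TAB> description
NCU05780	glutathione S-transferase-1
NCU09559	clock-controlled gene-9
NCU05770	catalase-2
NCU04930	hypothetical protein
NCU00355	catalase-3
NCU09674	O-methyltransferase family 3
NCU02812	uridylate kinase
NCU08402	zinc-binding alcohol dehydrogenase
NCU02727	glycine cleavage system T protein
NCU08004	electron transfer flavoprotein alpha-subunit
NCU06974	histidinol-phosphatase
NCU00685	casein kinase I isoform delta
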