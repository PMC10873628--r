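accession	gene	protein_name	function	subcellular_location	domains	interactors
PROT0001	GENE0001	Synthetic kinase 1	Phosphorylates synthetic substrates in the test pathway.	Cytoplasm	Kinase:20-280;UBA:300-340	PROT0002;PROT0003;PROT9999
PROT0002	GENE0002	Synthetic phosphatase 2	Dephosphorylates substrates of kinase 1.	Golgi apparatus	PP2C:15-250	PROT0001
PROT0003	GENE0003	Synthetic GTPase 3	Membrane trafficking switch of the synthetic pathway.	Endosome	GTPase:5-170	PROT0001;PROT0004
PTMP01	PGENE01	Synthetic phosphoprotein 1	Carrier of simulated phosphorylation sites.	Nucleus	Coiled coil:10-40	PTMP02
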