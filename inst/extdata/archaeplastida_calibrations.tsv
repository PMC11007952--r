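name	tip_a	tip_b	age_spec
Bangiomorpha	Porphyra_umbilicalis	Chondrus_crispus	1047 +13/-17
Oldest Florideophycidae	Chondrus_crispus	Gracilaria_chilensis	609 +/-5
Oldest Zygnemataceae	Spirogyra_pratensis	Zygnema_circumcarinatum	MIN: 350
First Land Plants	Marchantia_polymorpha	Arabidopsis_thaliana	MIN: 480
Oldest Tracheophytes	Selaginella_moellendorffii	Arabidopsis_thaliana	423-419
Fern-Seed Plant Split	Ceratopteris_richardii	Arabidopsis_thaliana	MIN: 385
Gymnosperm-Angiosperm Split	Picea_abies	Arabidopsis_thaliana	330-323
Amborella-Nymphaeales Split	Amborella_trichopoda	Arabidopsis_thaliana	129-125
Chloranthaceae-Magnoliid Split	Chloranthus_spicatus	Arabidopsis_thaliana	MIN: 125
Monocot-Eudicot Split	Oryza_sativa	Arabidopsis_thaliana	MIN: 113
Botryococcus braunii	Botryococcus_braunii	Chlamydomonas_reinhardtii	358-356
Proterocladus	Cladophora_glomerata	Ulva_mutabilis	1056-948
Vermiporella	Ulva_mutabilis	Chlamydomonas_reinhardtii	470-458
Protocodium	Codium_fragile	Caulerpa_lentillifera	MIN: 541
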