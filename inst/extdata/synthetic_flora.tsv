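# synthetic 30-taxon terrestrial flora (plus non-terrestrial palynomorph classes)
# every terrestrial taxon belongs to exactly one of 9 pollen-derived ecosystems
# and one of 13 plant functional groups; weights split ecosystem mass over taxa
taxon	ecological_class	ecosystem	pft_group	weight
Olea_type	terrestrial	medit_open_forest	warm_temp_evergreen	0.40
Pistacia_type	terrestrial	medit_open_forest	warm_temp_evergreen	0.25
Ceratonia_type	terrestrial	medit_open_forest	warm_temp_evergreen	0.20
Pinus_type	terrestrial	medit_open_forest	cool_conifer	0.15
Quercus_ithaburensis_type	terrestrial	quercus_ithaburensis_forest	temp_deciduous	0.55
Carpinus_type	terrestrial	quercus_ithaburensis_forest	temp_deciduous	0.25
Fraxinus_type	terrestrial	quercus_ithaburensis_forest	cool_mixed_forest	0.20
Poaceae_meadow	terrestrial	wet_meadow_steppe	wet_meadow_sedge	0.50
Ranunculaceae	terrestrial	wet_meadow_steppe	wet_meadow_sedge	0.30
Trifolium_type	terrestrial	wet_meadow_steppe	wet_meadow_sedge	0.20
Alnus_type	terrestrial	fen_trees	cool_mixed_forest	0.45
Salix_type	terrestrial	fen_trees	temp_deciduous	0.35
Platanus_type	terrestrial	fen_trees	temp_deciduous	0.20
Quercus_calliprinos_type	terrestrial	quercus_calliprinos_woodland	warm_temp_evergreen	0.50
Phillyrea_type	terrestrial	quercus_calliprinos_woodland	medit_shrub	0.30
Rhamnus_type	terrestrial	quercus_calliprinos_woodland	medit_shrub	0.20
Artemisia	terrestrial	shrub_steppe	cool_steppe_grass	0.40
Chenopodiaceae	terrestrial	shrub_steppe	desert_shrub	0.35
Ephedra_type	terrestrial	shrub_steppe	desert_shrub	0.25
Poaceae_steppe	terrestrial	dry_steppe	warm_steppe_grass	0.35
Aristida_type	terrestrial	dry_steppe	warm_steppe_grass	0.25
Zygophyllum_type	terrestrial	dry_steppe	hot_desert_forb	0.25
Calligonum_type	terrestrial	dry_steppe	hot_desert_forb	0.15
Sarcopoterium_type	terrestrial	phrygana_batha	medit_shrub	0.45
Cistus_type	terrestrial	phrygana_batha	medit_shrub	0.35
Thymelaea_type	terrestrial	phrygana_batha	medit_shrub	0.20
Cerealia_type	terrestrial	cultivated_urban	cool_steppe_grass	0.40
Plantago_type	terrestrial	cultivated_urban	cool_steppe_grass	0.25
Urtica_type	terrestrial	cultivated_urban	wet_meadow_sedge	0.15
Phoenix_type	terrestrial	cultivated_urban	trop_evergreen	0.20
Cyperaceae	hygro_hydrophyte	NA	NA	0.50
Typha_type	hygro_hydrophyte	NA	NA	0.30
Juncus_type	hygro_hydrophyte	NA	NA	0.20
Filicales_monolete	cryptogam_spore	NA	NA	0.70
Filicales_trilete	cryptogam_spore	NA	NA	0.30
Microcharcoal	microcharcoal	NA	NA	1.00
Dinocysts	dinocyst	NA	NA	1.00
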