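id	species	lineage_group	expected_class	family
Synechococcus_PKS	Synechococcus sp.	cyanobacterium	other_PKSIII	outgroup
Chrveli1|20057	Chromera velia	other_alga	other_PKSIII	algal_other_1
Pico_ML_1|52161	Picocystis sp.	other_alga	other_PKSIII	algal_other_1
Semro1|36990	Seminavis robusta	other_alga	other_PKSIII	algal_other_1
Ochro1393_1_4|754228	Ochromonas sp.	other_alga	other_PKSIII	algal_other_1
Ochro2298_1|456847	Ochromonadaceae sp.	other_alga	other_PKSIII	algal_other_1
Ochro2298_1|419265	Ochromonadaceae sp.	other_alga	other_PKSIII	algal_other_1
Ochro1393_1_4|932390	Ochromonas sp.	other_alga	other_PKSIII	algal_other_1
Ochro1393_1_4|179269	Ochromonas sp.	other_alga	other_PKSIII	algal_other_1
Mesen1|9713	Mesotaenium endlicherianum	charophyte	other_PKSIII	algal_other_1
Ectsil1|17490	Ectocarpus siliculosus	other_alga	other_PKSIII	algal_other_2
Claok1|5931	Cladosiphon okamuranus	other_alga	other_PKSIII	algal_other_2
Sacja1|7224	Saccharina japonica	other_alga	other_PKSIII	algal_other_2
Macpyr2|5041534	Macrocystis pyrifera	other_alga	other_PKSIII	algal_other_2
Undpi1|10741	Undaria pinnatifida	other_alga	other_PKSIII	algal_other_2
Alaesc1|15363	Alaria esculenta	other_alga	other_PKSIII	algal_other_2
MonC141_1|1230	Monodopsis strain	other_alga	other_PKSIII	algal_other_2
VisC74_1|13231	Vischeria strain	other_alga	other_PKSIII	algal_other_2
Ochro1393_1_4|905391	Ochromonas sp.	other_alga	other_PKSIII	algal_other_3
Ochro2298_1|408009	Ochromonadaceae sp.	other_alga	other_PKSIII	algal_other_3
Ochro2298_1|458546	Ochromonadaceae sp.	other_alga	other_PKSIII	algal_other_3
Pelago2097_1|478370	Pelagophyceae sp.	other_alga	other_PKSIII	algal_other_3
Ectsil1|30595	Ectocarpus siliculosus	other_alga	other_PKSIII	algal_other_4
Claok1|7458	Cladosiphon okamuranus	other_alga	other_PKSIII	algal_other_4
Macpyr2|9688433	Macrocystis pyrifera	other_alga	other_PKSIII	algal_other_4
Sacja1|14235	Saccharina japonica	other_alga	other_PKSIII	algal_other_4
Alaesc1|3438	Alaria esculenta	other_alga	other_PKSIII	algal_other_4
Undpi1|3722	Undaria pinnatifida	other_alga	other_PKSIII	algal_other_4
Undpi1|3721	Undaria pinnatifida	other_alga	other_PKSIII	algal_other_4
SymretSc1|46235	Symbiochloris reticulata	other_alga	other_PKSIII	algal_other_5
Coccomyxa_PKS	Coccomyxa subellipsoidea	other_alga	other_PKSIII	algal_other_5
Sceob152z_1|1656	Scenedesmus obliquus	other_alga	other_PKSIII	algal_other_5
Tetrob172_l|3940502	Tetradesmus obliquus	other_alga	other_PKSIII	algal_other_5
Spimu1|9263	Spirogloea muscicola	charophyte	other_PKSIII	algal_other_5
Spimu1|2401	Spirogloea muscicola	charophyte	other_PKSIII	algal_other_5
Spimu1|17478	Spirogloea muscicola	charophyte	other_PKSIII	algal_other_5
Meskra|3110107	Mesotaenium kramstae	charophyte	ORS	algal_ORS
Spimu1|13141	Spirogloea muscicola	charophyte	ORS	algal_ORS
Spimu1|13204	Spirogloea muscicola	charophyte	ORS	algal_ORS
Zygcyl6981a_1|20083	Zygnema cf. cylindricum	charophyte	ORS	algal_ORS
Zygcir1559_1|1602	Zygnema circumcarinatum	charophyte	ORS	algal_ORS
Zygcir1559_1|1600	Zygnema circumcarinatum	charophyte	ORS	algal_ORS
Meskra|2213449	Mesotaenium kramstae	charophyte	ORS	algal_ORS
Meskra|2284394	Mesotaenium kramstae	charophyte	ORS	algal_ORS
Penium|pm001652g0050	Penium margaritaceum	charophyte	ORS	algal_ORS
Penium|pm022924g0020	Penium margaritaceum	charophyte	ORS	algal_ORS
Penium|pm001997g0040	Penium margaritaceum	charophyte	ORS	algal_ORS
Penium|pm003016g0080	Penium margaritaceum	charophyte	ORS	algal_ORS
CepurGG1.6G090700	Ceratodon purpureus	bryophyte	ORS	bryophyte_ORS
CepurGG1.2G039900	Ceratodon purpureus	bryophyte	ORS	bryophyte_ORS
PpORS	Physcomitrium patens	bryophyte	ORS	bryophyte_ORS
AANG005398	Anthoceros angustus	bryophyte	ORS	bryophyte_ORS
Takakia_Tle2c02540.1	Takakia lepidozioides	bryophyte	ORS	bryophyte_ORS
Takakia_Tle3c00272.1	Takakia lepidozioides	bryophyte	ORS	bryophyte_ORS
CepurGG1.8G019400	Ceratodon purpureus	bryophyte	ORS	bryophyte_ORS
Pohlia_PKS2	Pohlia nutans	bryophyte	ORS	bryophyte_ORS
Phypa_126819	Physcomitrium patens	bryophyte	ORS	bryophyte_ORS
CepurGG1.9G130000	Ceratodon purpureus	bryophyte	ORS	bryophyte_ORS
Pohlia_PKS1	Pohlia nutans	bryophyte	ORS	bryophyte_ORS
AANG008114	Anthoceros angustus	bryophyte	ASCL	embryophyte_ASCL
Mp1g11030	Marchantia polymorpha	bryophyte	ASCL	embryophyte_ASCL
Takakia_Tle1c06550.1	Takakia lepidozioides	bryophyte	ASCL	embryophyte_ASCL
Sphfalx16G090200	Sphagnum fallax	bryophyte	ASCL	embryophyte_ASCL
Sphfalx20G004200	Sphagnum fallax	bryophyte	ASCL	embryophyte_ASCL
CepurGG1.N016500	Ceratodon purpureus	bryophyte	ASCL	embryophyte_ASCL
PpASCL	Physcomitrium patens	bryophyte	ASCL	embryophyte_ASCL
Selmo1:122361	Selaginella moellendorffii	other_embryophyte	ASCL	embryophyte_ASCL
Ceratopteris_PKS	Ceratopteris richardii	other_embryophyte	ASCL	embryophyte_ASCL
PrCHSL	Pinus radiata	other_embryophyte	ASCL	embryophyte_ASCL
AtPKSA	Arabidopsis thaliana	other_embryophyte	ASCL	embryophyte_ASCL
AtPKSB	Arabidopsis thaliana	other_embryophyte	ASCL	embryophyte_ASCL
Os10g0484800_YY2	Oryza sativa	other_embryophyte	ASCL	embryophyte_ASCL
Os07g0411300	Oryza sativa	other_embryophyte	ASCL	embryophyte_ASCL
Takakia_Tle2c05338.1	Takakia lepidozioides	bryophyte	other_PKSIII	embryophyte_other
PpCHS	Physcomitrium patens	bryophyte	other_PKSIII	embryophyte_other
Mp4g23190	Marchantia polymorpha	bryophyte	other_PKSIII	embryophyte_other
AANG010604	Anthoceros angustus	bryophyte	other_PKSIII	embryophyte_other
MsCHS2	Medicago sativa	other_embryophyte	other_PKSIII	embryophyte_other
AhSTS	Arachis hypogaea	other_embryophyte	other_PKSIII	embryophyte_other
Gh2PS	Gerbera hybrid cultivar	other_embryophyte	other_PKSIII	embryophyte_other
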