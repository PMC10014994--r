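species_id,abundance_ind_ha,sites,dominance_m2_ha
opuntia_streptacantha,609,49,119.6
ipomoea_wolcottiana,74,30,920.3
ceiba_aesculifolia,26,12,808.2
acacia_pennatula,113,29,227.1
bursera_bipinnata,33,17,440.1
lonchocarpus_caudatus,94,11,327.1
stenocereus_griseus,96,24,108.9
stenocereus_stellatus,104,27,39.9
acacia_farnesiana,69,24,155.5
echinocactus_platyacanthus,148,18,18.6
mimosa_benthamii,70,11,159.7
piptadenia_viridiflora,46,13,192.4
acacia_coulteri,30,14,209.4
bunchosia_lanceolata,91,12,25.6
acacia_cochliacantha,59,12,67.0
bursera_copallifera,15,8,205.3
styphnolobium_burseroides,9,5,147.3
pithecellobium_acatlense,24,8,42.5
agave_ghiesbreghtii,26,5,20.4
cyrtocarpa_procera,2,1,105.1
marsdenia_zimapanica,17,4,10.6
celtis_caudata,6,2,47.5
conzattia_multiflora,2,1,46.0
cassia_emarginata,17,1,2.1
bursera_aptera,2,1,36.4
lysiloma_divaricatum,2,1,29.4
bursera_aloexylon,2,1,23.3
heliocarpus_terebinthinaceus,4,1,18.2
agave_karwinskii,4,1,4.2
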