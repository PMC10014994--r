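species_id,scientific_name,common_name,genus,family,life_form
cyrtocarpa_procera,Cyrtocarpa procera,Coco de cerro,Cyrtocarpa,Anacardiaceae,tree
marsdenia_zimapanica,Marsdenia zimapanica,Tecuampatli,Marsdenia,Apocynaceae,climber
agave_ghiesbreghtii,Agave ghiesbreghtii,Maguey,Agave,Asparagaceae,acaulescent_rosette
agave_karwinskii,Agave karwinskii,Maguey oscuro,Agave,Asparagaceae,acaulescent_rosette
ceiba_aesculifolia,Ceiba aesculifolia,Pochote,Ceiba,Bombacaceae,tree
bursera_aloexylon,Bursera aloexylon,Linaloe,Bursera,Burseraceae,tree
bursera_aptera,Bursera aptera,Cuajiote amarillo,Bursera,Burseraceae,tree
bursera_bipinnata,Bursera bipinnata,Copal chino,Bursera,Burseraceae,tree
bursera_copallifera,Bursera copallifera,Copal,Bursera,Burseraceae,tree
echinocactus_platyacanthus,Echinocactus platyacanthus,Biznaga,Echinocactus,Cactaceae,succulent
opuntia_streptacantha,Opuntia streptacantha,Nopal,Opuntia,Cactaceae,succulent
stenocereus_griseus,Stenocereus griseus,Pitayo,Stenocereus,Cactaceae,succulent
stenocereus_stellatus,Stenocereus stellatus,Pitayo,Stenocereus,Cactaceae,succulent
celtis_caudata,Celtis caudata,Palo sosonaco,Celtis,Cannabaceae,tree
ipomoea_wolcottiana,Ipomoea wolcottiana,Cazahuate,Ipomoea,Convolvulaceae,tree
acacia_cochliacantha,Acacia cochliacantha,Cubata negra,Acacia,Fabaceae,shrub
acacia_coulteri,Acacia coulteri,Palo blanco,Acacia,Fabaceae,tree
acacia_farnesiana,Acacia farnesiana,Huizache,Acacia,Fabaceae,shrub
acacia_pennatula,Acacia pennatula,Cubata blanca,Acacia,Fabaceae,shrub
conzattia_multiflora,Conzattia multiflora,Palo totole,Conzattia,Fabaceae,tree
lonchocarpus_caudatus,Lonchocarpus caudatus,Tapachichi,Lonchocarpus,Fabaceae,tree
lysiloma_divaricatum,Lysiloma divaricatum,Tlahuitolo,Lysiloma,Fabaceae,tree
mimosa_benthamii,Mimosa benthamii,Tecolhuixtle,Mimosa,Fabaceae,shrub
piptadenia_viridiflora,Piptadenia viridiflora,Huamuchilillo,Piptadenia,Fabaceae,tree
pithecellobium_acatlense,Pithecellobium acatlense,Barba de chivo,Pithecellobium,Fabaceae,shrub
styphnolobium_burseroides,Styphnolobium burseroides,Pico de pajaro,Styphnolobium,Fabaceae,shrub
cassia_emarginata,Cassia emarginata,Vara de san Jose,Cassia,Fabaceae,shrub
bunchosia_lanceolata,Bunchosia lanceolata,Nanche de zorro,Bunchosia,Malpighiaceae,shrub
heliocarpus_terebinthinaceus,Heliocarpus terebinthinaceus,Calahuate,Heliocarpus,Tiliaceae,shrub
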