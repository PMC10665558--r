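# Species-median cerebello-cerebral volumes for 34 primate species, compiled
# from a published open comparative-MRI resource (manual segmentations of 63
# cerebella and 30 ansiform areas; 9 infraorders). Volumes in mm3. Median
# absolute deviations (raw MAD, no consistency factor) are printed only for
# the six species with >= 4 specimens; ansiform MADs exist only for human and
# chimpanzee. ratio_* columns are the ratios as printed in the source table
# (percent, 2 dp): cerebellum/cerebrum and ansiform/cerebellum. For
# multi-specimen species the printed ratio is the median of per-specimen
# ratios (with its MAD), not the ratio of medians. *_verified = 1 marks cells
# that reproduce exactly (half-away-from-zero rounding, 2 dp) from the printed
# medians; 0-cells were evidently computed from unrounded specimen data and
# are frozen as non-recomputable. The cerebral volume of the white-faced
# sapajou was reconstructed as 40051 from the printed ratio (the source
# table's typography is ambiguous for that cell). outlier_note records the
# source's boxplot/Shapiro-Wilk screen: one rhesus and one crab-eating macaque
# specimen were excluded from analyses as cerebellar/cerebral outliers.
# These values are literal constants: never regenerated at runtime.
common_name,species,n_specimens,cerebellum_mm3,cerebrum_mm3,ansiform_mm3,cerebellum_mad_mm3,cerebrum_mad_mm3,ansiform_mad_mm3,ratio_cbl_cbr_printed,ratio_cbl_cbr_mad,ratio_ans_cbl_printed,ratio_ans_cbl_mad,ratio_cbl_cbr_verified,ratio_ans_cbl_verified,suborder,is_ape,outlier_note
Demidoff's galago,Galago_demidoff,1,320,1925,NA,NA,NA,NA,16.65,NA,NA,NA,0,NA,strepsirrhine,0,
Red slender loris,Loris_tardigradus,1,447,3071,NA,NA,NA,NA,14.54,NA,NA,NA,0,NA,strepsirrhine,0,
Aye-aye,Daubentonia_madagascariensis,1,3032,17151,374,NA,NA,NA,17.68,NA,12.33,NA,1,0,strepsirrhine,0,
Black-and-white ruffed lemur,Varecia_variegata,1,3377,16032,NA,NA,NA,NA,21.06,NA,NA,NA,1,NA,strepsirrhine,0,
Ring-tailed lemur,Lemur_catta,1,2035,12658,NA,NA,NA,NA,16.08,NA,NA,NA,1,NA,strepsirrhine,0,
Mongoose lemur,Eulemur_mongoz,1,3224,14495,NA,NA,NA,NA,22.24,NA,NA,NA,1,NA,strepsirrhine,0,
Red-tailed sportive lemur,Lepilemur_ruficaudatus,1,882,4087,NA,NA,NA,NA,21.59,NA,NA,NA,0,NA,strepsirrhine,0,
Coquerel's mouse lemur,Mirza_coquereli,1,884,3885,NA,NA,NA,NA,22.75,NA,NA,NA,1,NA,strepsirrhine,0,
Gray mouse lemur,Microcebus_murinus,1,170,809,NA,NA,NA,NA,20.99,NA,NA,NA,0,NA,strepsirrhine,0,
Squirrel monkey,Saimiri_sciureus,2,920,8540,103,55,1263,NA,10.93,2.26,11.20,NA,0,1,haplorhine,0,
Tufted capuchin,Cebus_apella,1,5191,36285,1012,NA,NA,NA,14.31,NA,19.50,NA,1,1,haplorhine,0,
White-faced sapajou,Cebus_capucinus,1,4274,40051,NA,NA,NA,NA,10.67,NA,NA,NA,1,NA,haplorhine,0,
Cotton-top tamarin,Saguinus_oedipus,1,750,6254,NA,NA,NA,NA,11.99,NA,NA,NA,1,NA,haplorhine,0,
Black-pencilled marmoset,Callithrix_penicillata,1,485,3938,NA,NA,NA,NA,12.31,NA,NA,NA,0,NA,haplorhine,0,
Douroucouli,Aotus_trivirgatus,1,1627,11746,217,NA,NA,NA,13.85,NA,13.31,NA,1,0,haplorhine,0,
Wooly monkey,Lagothrix_lagotricha,1,5595,49385,874,NA,NA,NA,11.33,NA,15.62,NA,1,1,haplorhine,0,
Black spider monkey,Ateles_paniscus,2,8903,77381,NA,1411,10948,NA,11.49,0.20,NA,NA,0,NA,haplorhine,0,
Orangutan,Pongo_pygmaeus,1,25757,184458,6081,NA,NA,NA,13.96,NA,23.61,NA,1,1,haplorhine,1,
Chimpanzee,Pan_troglodytes,9,57047,284482,15544,6915,26063,1932,18.36,3.56,27.25,3.69,0,1,haplorhine,1,
Bonobo,Pan_paniscus,1,48408,243036,6627,NA,NA,NA,19.92,NA,13.69,NA,1,1,haplorhine,1,
Human,Homo_sapiens,10,142171,1005711,43726,18710,179368,5003,14.26,1.75,30.76,1.91,0,1,haplorhine,1,
Western lowland gorilla,Gorilla_gorilla_gorilla,1,58402,237690,13107,NA,NA,NA,24.57,NA,22.44,NA,1,1,haplorhine,1,
Eastern gorilla,Gorilla_beringei,1,46163,272908,NA,NA,NA,NA,16.92,NA,NA,NA,1,NA,haplorhine,1,
Gibbon,Hylobates_lar,1,8681,60685,NA,NA,NA,NA,14.31,NA,NA,NA,1,NA,haplorhine,1,
Indochinese lutung,Trachypithecus_germaini,1,3756,37988,NA,NA,NA,NA,9.89,NA,NA,NA,1,NA,haplorhine,0,
Hanuman langur,Semnopithecus_entellus,1,6749,49916,NA,NA,NA,NA,13.52,NA,NA,NA,1,NA,haplorhine,0,
King colobus,Colobus_polykomos,1,5787,40468,842,NA,NA,NA,14.30,NA,14.55,NA,1,1,haplorhine,0,
Rhesus macaque,Macaca_mulatta,6,10456,75928,NA,500,4689,NA,13.54,0.64,NA,NA,0,NA,haplorhine,0,one specimen excluded as cerebellar/cerebral outlier
Crab-eating macaque,Macaca_fascicularis,8,6184,46286,NA,955,9597,NA,12.89,0.98,NA,NA,0,NA,haplorhine,0,one specimen excluded as cerebellar/cerebral outlier
Hamadryas baboon,Papio_hamadryas,1,9478,89861,1841,NA,NA,NA,10.55,NA,19.42,NA,1,1,haplorhine,0,
Gray-cheeked mangabey,Lophocebus_albigena,1,6320,49185,NA,NA,NA,NA,12.85,NA,NA,NA,1,NA,haplorhine,0,
Sooty mangabey,Cercocebus_atys,1,5362,51689,NA,NA,NA,NA,10.37,NA,NA,NA,1,NA,haplorhine,0,
Green monkey,Chlorocebus_aethiops,1,4169,53627,505,NA,NA,NA,7.77,NA,12.11,NA,1,1,haplorhine,0,
Moustached guenon,Cercopithecus_cephus,1,3697,41538,NA,NA,NA,NA,8.90,NA,NA,NA,1,NA,haplorhine,0,
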