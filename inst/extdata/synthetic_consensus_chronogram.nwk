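[SYNTHETIC chronogram: a stand-in time-calibrated consensus phylogeny for the 34 study species, assembled once from standard published primate divergence-time estimates (branch lengths in millions of years; root depth 74 My). It is NOT the 10kTrees consensus tree; download that separately for exact reproductions.]
(((Galago_demidoff:40,Loris_tardigradus:40):23,(Daubentonia_madagascariensis:50,((Varecia_variegata:25,(Lemur_catta:18,Eulemur_mongoz:18):7):13,(Lepilemur_ruficaudatus:30,(Mirza_coquereli:25,Microcebus_murinus:25):5):8):12):13):11,(((Lagothrix_lagotricha:11,Ateles_paniscus:11):14,(Aotus_trivirgatus:23,(((Cebus_apella:6,Cebus_capucinus:6):8,Saimiri_sciureus:14):6,(Saguinus_oedipus:13,Callithrix_penicillata:13):7):3):2):18,((Hylobates_lar:20,(Pongo_pygmaeus:17,((Gorilla_gorilla_gorilla:1.2,Gorilla_beringei:1.2):7.8,(Homo_sapiens:7,(Pan_troglodytes:2.5,Pan_paniscus:2.5):4.5):2):8):3):10,((Colobus_polykomos:13,(Trachypithecus_germaini:9,Semnopithecus_entellus:9):4):5,((Chlorocebus_aethiops:9,Cercopithecus_cephus:9):3,((Macaca_mulatta:3.5,Macaca_fascicularis:3.5):6.5,((Papio_hamadryas:6,Lophocebus_albigena:6):2,Cercocebus_atys:8):2):2):6):12):13):31);
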