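specimen_id,taxon,clade,porosity,lifestyle,region,ornamented,age,collection_number
Araripesuchus_tsangatsangana,Araripesuchus tsangatsangana,Pseudosuchia,0.05,terrestrial,n.a.,yes,Late Cretaceous,UA 9966
Batrachotomus_kupferzellensis,Batrachotomus kupferzellensis,Pseudosuchia,0.01,terrestrial,paramedian pre-caudal,yes,Late Ladinian,SMNS 80317
Prestosuchus_chiniquensis,Prestosuchus chiniquensis,Pseudosuchia,0.05,terrestrial,sacral paramedian,yes,Late Ladinian/Early Carnian,BSPG ASXXV7
Prestosuchus_loricatus,'Prestosuchus' loricatus,Pseudosuchia,0.04,terrestrial,pre-caudal paramedian,yes,Late Ladinian/Early Carnian,BSPG ASXXV46d
Rauisuchus_tiradentes,Rauisuchus tiradentes,Pseudosuchia,0.16,terrestrial,pre-caudal paramedian,yes,Late Carnian/Early Norian,BSPG ASXXV121b
Revueltosaurus_sp,Revueltosaurus sp.,Pseudosuchia,0.04,terrestrial,paramedian,yes,Norian,PEFO 33787
Tikisuchus_romeri,Tikisuchus romeri,Pseudosuchia,0.14,terrestrial,pre-caudal paramedian,yes,Carnian,ISI R 305/ 1
Simosuchus_clarki_1,Simosuchus clarki,Pseudosuchia,0.1,terrestrial,n.a.,no,Late Cretaceous,UA 9965
Simosuchus_clarki_2,Simosuchus clarki,Pseudosuchia,0.07,terrestrial,n.a.,no,Late Cretaceous,UA 9965
Yarasuchus_deccanensis,Yarasuchus deccanensis,Avemetatarsalia-outgroup,0.10,terrestrial,pre-caudal paramedian,yes,Anisian,ISI R 334
Alligator_mississippiensis,Alligator mississippiensis,Pseudosuchia,0.15,semi-aquatic,n.a.,yes,extant,SMNS 10481b
Allognathosuchus_wartheni,Allognathosuchus wartheni,Pseudosuchia,0.13,semi-aquatic,n.a.,yes,Wasatchian,UCMP 113731
Crocodylus_niloticus,Crocodylus niloticus,Pseudosuchia,0.13,semi-aquatic,dorsal,yes,extant,"MNHN-AC- 1920.90, PC"
Diplocynodon_sp,Diplocynodon sp.,Pseudosuchia,0.23,semi-aquatic,n.a.,yes,Eocene-Miocene,IPB R144 / 1
Diplocynodon_remensis,Diplocynodon remensis,Pseudosuchia,0.24,semi-aquatic,nuchal,yes,Thanetian,MNHN. F. No number
Machimosaurus_hugii,Machimosaurus hugii,Pseudosuchia,0.22,semi-aquatic,n.a.,yes,Late Jurassic,SMNS 81608
Sarcosuchus_imperator,Sarcosuchus imperator,Pseudosuchia,0.24,semi-aquatic,n.a.,yes,Upper Cretaceous,MNHN.F. GDF 380
Steneosaurus_sp,Steneosaurus sp.,Pseudosuchia,0.07,semi-aquatic,n.a.,yes,Late Jurassic,NMS 752
Steneosaurus_jugleri,Steneosaurus jugleri,Pseudosuchia,0.12,semi-aquatic,n.a.,yes,Late Jurassic,NMS 7152
Paleosuchus_trigonatus,Paleosuchus trigonatus,Pseudosuchia,0.29,semi-aquatic,n.a.,yes,extant,MCL 420003939
Protocaiman_peligrensis,Protocaiman peligrensis,Pseudosuchia,0.13,semi-aquatic,n.a.,yes,Danian,UCMP 131693
Teleosaurus_cadomensis,Teleosaurus cadomensis,Pseudosuchia,0.22,semi-aquatic,n.a.,yes,Bathonian,MNHN Histo 1960
Goniopholis_sp,Goniopholis sp.,Pseudosuchia,0.2,semi-aquatic,n.a.,yes,Oxfordian-Berriasian,MNHN Histo 1727
Borealosuchus_sp,Borealosuchus sp.,Pseudosuchia,0.17,semi-aquatic,n.a,yes,Campanian-Ypresian,UCMP 133903
Mahajangasuchus_insignis,Mahajangasuchus insignis,Pseudosuchia,0.17,semi-aquatic,n.a.,yes,Campanian,UA 9962
Brachychampsa_montana,Brachychampsa montana,Pseudosuchia,0.22,semi-aquatic,n.a.,yes,Maastrichtian,UCMP 133901
Osteolaemus_tetraspis,Osteolaemus tetraspis,Pseudosuchia,0.12,semi-aquatic,n.a.,yes,extant,MNHN-AC-1991.4488
Paleosuchus_palpebrosus,Paleosuchus palpebrosus,Pseudosuchia,0.11,semi-aquatic,n.a.,yes,extant,MNHN.AC-1909.204
Caiman_crocodilus,Caiman crocodilus,Pseudosuchia,0.27,semi-aquatic,nuchal,yes,extant,Sorbonne Universite - NA
Borealosuchus_wilsoni,Borealosuchus wilsoni,Pseudosuchia,0.18,semi-aquatic,n.a.,yes,Ypresian,UCMP 131696
Paratypothorax_sp,Paratypothorax sp.,Pseudosuchia,0.25,terrestrial,paramedian,yes,Late Triassic,PEFO 5030
Aetosaurus_scagliai,Aetosaurus scagliai,Pseudosuchia,0.05,terrestrial,paramedian,yes,Late Triassic,PVL 2073
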