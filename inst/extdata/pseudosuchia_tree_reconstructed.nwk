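(Yarasuchus_deccanensis:5.0,((Revueltosaurus_sp:15.0,(Paratypothorax_sp:15.0,Aetosaurus_scagliai:15.0):5.0):18.0,((Batrachotomus_kupferzellensis:2.0,(Prestosuchus_chiniquensis:2.0,Prestosuchus_loricatus:2.0):2.0):3.0,((Rauisuchus_tiradentes:8.0,Tikisuchus_romeri:4.0):6.0,((Araripesuchus_tsangatsangana:50.0,(Simosuchus_clarki:32.0,Mahajangasuchus_insignis:25.0):20.0):115.0,((Teleosaurus_cadomensis:13.0,(Machimosaurus_hugii:25.0,(Steneosaurus_sp:15.0,Steneosaurus_jugleri:15.0):10.0):5.0):20.0,(Sarcosuchus_imperator:50.0,(Goniopholis_sp:5.0,((Borealosuchus_sp:35.0,Borealosuchus_wilsoni:43.0):15.0,((Crocodylus_niloticus:82.0,Osteolaemus_tetraspis:82.0):8.0,((Diplocynodon_sp:45.0,Diplocynodon_remensis:18.0):10.0,(Brachychampsa_montana:12.0,((Allognathosuchus_wartheni:12.0,Alligator_mississippiensis:64.0):8.0,(Protocaiman_peligrensis:1.0,(Caiman_crocodilus:40.0,(Paleosuchus_trigonatus:20.0,Paleosuchus_palpebrosus:20.0):20.0):22.0):10.0):8.0):5.0):5.0):20.0):45.0):5.0):40.0):35.0):7.0):2.0):4.0):2.0);
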