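((Solemys_sp:33.0,Solemys_vermiculata:33.0):80.0,(Plesiochelys_sp:17.0,((Dorkota_vasconica:13.0,(Podocnemis_erythrocephala:125.0,(Bothremys_barberi:15.0,Taphrosphys_sulcatus:23.0):35.0):15.0):28.0,((Carettochelys_insculpta:140.0,(Pelodiscus_sinensis:125.0,Trionychidae_indet:20.0):15.0):22.0,((Caretta_caretta:110.0,(Archelon_ischyros:15.0,Ctenochelys_stenoporus:10.0):25.0):40.0,(Terrapene_carolina_tringuis:100.0,(Geochelone_elegans:50.0,(Hesperotestudo_sp:9.0,Hesperotestudo_crassiscuta:9.0):40.0):50.0):50.0):12.0):6.0):4.0):8.0);
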