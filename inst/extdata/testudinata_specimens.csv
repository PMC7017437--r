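specimen_id,taxon,clade,porosity,lifestyle,region,ornamented,age,collection_number
Hesperotestudo_sp_1,Hesperotestudo sp.,Testudinata,0.07,terrestrial,flat osteoderm,no,Pleistocene,TMM 30967-1010.1
Hesperotestudo_sp_2,Hesperotestudo sp.,Testudinata,0.21,terrestrial,spiked osteoderm,no,Pleistocene,TMM 30967-1010.2
Terrapene_carolina_tringuis_1,Terrapene carolina tringuis,Testudinata,0.40,terrestrial,neural,no,extant,FMNH 211806
Terrapene_carolina_tringuis_2,Terrapene carolina tringuis,Testudinata,0.22,terrestrial,costal (right),no,extant,FMNH 211806
Dorkota_vasconica_1,Dorkota vasconica,Testudinata,0.21,freshwater,costal,no,Barremian,MCNA 14366
Dorkota_vasconica_2,Dorkota vasconica,Testudinata,0.24,freshwater,neural,no,Barremian,MCNA 14372
Podocnemis_erythrocephala,Podocnemis erythrocephala,Testudinata,0.15,freshwater,sample costal,no,extant,YPM 11853
Solemys_sp,Solemys sp.,Testudinata,0.07,terrestrial,costal fragment,yes,Maastrichtyian,UPUAM-14001
Solemys_vermiculata_1,Solemys vermiculata,Testudinata,0.14,terrestrial,costal fragment,yes,Maastrichtyian,MCNA 15047
Solemys_vermiculata_2,Solemys vermiculata,Testudinata,0.16,terrestrial,shell fragment,yes,Maastrichtyian,MCNA 15046
Carettochelys_insculpta,Carettochelys insculpta,Testudinata,0.10,freshwater,costal (right 7th),yes,extant,WU-SILS RH1044
Pelodiscus_sinensis,Pelodiscus sinensis,Testudinata,0.11,freshwater,costal,yes,extant,NSMT-H 6600
Trionychidae_indet_1,Trionychidae indet.,Testudinata,0.11,freshwater,costal,yes,Aptian-Albian,ZIN PH 102
Trionychidae_indet_2,Trionychidae indet.,Testudinata,0.10,freshwater,costal,yes,early Cenomanian,ZIN PH 122
Trionychidae_indet_3,Trionychidae indet.,Testudinata,0.09,freshwater,costal,yes,Barremian-Aptian,FPDM V0127
Bothremys_barberi_1,Bothremys barberi,Testudinata,0.31,marine,costal,no,Campanian,FM P27406 (FMNH)
Bothremys_barberi_2,Bothremys barberi,Testudinata,0.32,marine,costal,no,Campanian,FM P27406 (FMNH)
Bothremys_barberi_3,Bothremys barberi,Testudinata,0.30,marine,neural,no,Campanian,FM P27406 (FMNH)
Caretta_caretta_1,Caretta caretta,Testudinata,0.39,marine,costal,no,extant,FMNH 98963
Caretta_caretta_2,Caretta caretta,Testudinata,0.33,marine,hyoplastron,no,extant,FMNH 98963
Archelon_ischyros,Archelon ischyros,Testudinata,0.26,marine,shell fragment,no,Late Cretaceous,YPM 1783
Plesiochelys_sp,Plesiochelys sp.,Testudinata,0.18,marine,neural,no,Kimmeridgian,NMS 8730
Taphrosphys_sulcatus_1,Taphrosphys sulcatus,Testudinata,0.34,marine,costal,no,Maastrichtian,YPM 40288
Taphrosphys_sulcatus_2,Taphrosphys sulcatus,Testudinata,0.35,marine,neural,no,Maastrichtian,YPM 40288
Ctenochelys_stenoporus,Ctenochelys stenoporus,Testudinata,0.36,marine,neural,no,Campanian,FM PR 442
Geochelone_elegans_1,Geochelone elegans,Testudinata,0.14,terrestrial,costal,no,extant,IPB 561-C
Geochelone_elegans_2,Geochelone elegans,Testudinata,0.10,terrestrial,costal,no,extant,IPB 561-C
Geochelone_elegans_3,Geochelone elegans,Testudinata,0.07,terrestrial,neural,no,extant,IPB 561-C
Hesperotestudo_crassiscuta_1,Hesperotestudo crassiscuta,Testudinata,0.19,terrestrial,neural,no,Pleistocene,ROM 5540
Hesperotestudo_crassiscuta_2,Hesperotestudo crassiscuta,Testudinata,0.30,terrestrial,plaston fragment,no,Pleistocene,ROM 5541
Hesperotestudo_crassiscuta_3,Hesperotestudo crassiscuta,Testudinata,0.28,terrestrial,shell fragment,no,Pleistocene,ROM 5542
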