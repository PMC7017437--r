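# Build coarse "reconstructed" species-level chronogram fixtures.
# Node spec: list(age=<Ma before present>, children=list(...)) or list(age=, label=).
# Branch length = parent age - child age (Myr). Run once; output committed as text.

leaf <- function(label, age) list(age = age, label = label)
nd <- function(age, ...) list(age = age, children = list(...))

to_newick <- function(node, parent_age = NULL) {
  s <- if (!is.null(node$children)) {
    paste0("(", paste(vapply(node$children, to_newick, "", parent_age = node$age),
                      collapse = ","), ")")
  } else node$label
  if (is.null(parent_age)) return(paste0(s, ";"))
  bl <- parent_age - node$age
  stopifnot(bl >= 0)
  paste0(s, ":", format(bl, nsmall = 1))
}

## Pseudosuchia (+ Yarasuchus as avemetatarsalian outgroup), root ~250 Ma
pseudo <- nd(250,
  leaf("Yarasuchus_deccanensis", 245),
  nd(248,
    nd(230,
      leaf("Revueltosaurus_sp", 215),
      nd(225, leaf("Paratypothorax_sp", 210), leaf("Aetosaurus_scagliai", 210))),
    nd(244,
      nd(241,
        leaf("Batrachotomus_kupferzellensis", 239),
        nd(239, leaf("Prestosuchus_chiniquensis", 237), leaf("Prestosuchus_loricatus", 237))),
      nd(242,
        nd(236, leaf("Rauisuchus_tiradentes", 228), leaf("Tikisuchus_romeri", 232)),
        nd(235,
          nd(120,
            leaf("Araripesuchus_tsangatsangana", 70),
            nd(100, leaf("Simosuchus_clarki", 68), leaf("Mahajangasuchus_insignis", 75))),
          nd(200,
            nd(180,
              leaf("Teleosaurus_cadomensis", 167),
              nd(175,
                leaf("Machimosaurus_hugii", 150),
                nd(165, leaf("Steneosaurus_sp", 150), leaf("Steneosaurus_jugleri", 150)))),
            nd(160,
              leaf("Sarcosuchus_imperator", 110),
              nd(155,
                leaf("Goniopholis_sp", 150),
                nd(110,
                  nd(95, leaf("Borealosuchus_sp", 60), leaf("Borealosuchus_wilsoni", 52)),
                  nd(90,
                    nd(82, leaf("Crocodylus_niloticus", 0), leaf("Osteolaemus_tetraspis", 0)),
                    nd(85,
                      nd(75, leaf("Diplocynodon_sp", 30), leaf("Diplocynodon_remensis", 57)),
                      nd(80,
                        leaf("Brachychampsa_montana", 68),
                        nd(72,
                          nd(64, leaf("Allognathosuchus_wartheni", 52),
                                 leaf("Alligator_mississippiensis", 0)),
                          nd(62,
                            leaf("Protocaiman_peligrensis", 61),
                            nd(40,
                              leaf("Caiman_crocodilus", 0),
                              nd(20, leaf("Paleosuchus_trigonatus", 0),
                                     leaf("Paleosuchus_palpebrosus", 0)))))))))))))))))

## Testudinata, root ~180 Ma
testu <- nd(180,
  nd(100, leaf("Solemys_sp", 67), leaf("Solemys_vermiculata", 67)),
  nd(172,
    leaf("Plesiochelys_sp", 155),
    nd(168,
      nd(140,
        leaf("Dorkota_vasconica", 127),
        nd(125,
          leaf("Podocnemis_erythrocephala", 0),
          nd(90, leaf("Bothremys_barberi", 75), leaf("Taphrosphys_sulcatus", 67)))),
      nd(162,
        nd(140,
          leaf("Carettochelys_insculpta", 0),
          nd(125, leaf("Pelodiscus_sinensis", 0), leaf("Trionychidae_indet", 105))),
        nd(150,
          nd(110,
            leaf("Caretta_caretta", 0),
            nd(85, leaf("Archelon_ischyros", 70), leaf("Ctenochelys_stenoporus", 75))),
          nd(100,
            leaf("Terrapene_carolina_tringuis", 0),
            nd(50,
              leaf("Geochelone_elegans", 0),
              nd(10, leaf("Hesperotestudo_sp", 1),
                     leaf("Hesperotestudo_crassiscuta", 1)))))))))

library(ape)
for (x in list(c("pseudosuchia", "pseudo"), c("testudinata", "testu"))) {
  nwk <- to_newick(get(x[2]))
  tr <- read.tree(text = nwk)
  stopifnot(is.rooted(tr), all(tr$edge.length >= 0))
  cat(x[1], ": ", Ntip(tr), " tips, max depth ",
      max(node.depth.edgelength(tr)), "\n", sep = "")
  writeLines(nwk, file.path("inst/extdata",
             paste0(x[1], "_tree_reconstructed.nwk")))
}
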