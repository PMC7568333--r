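# Synthetic example chronogram and clade map used by the examples, tests
# and the simulation studies. The topology mirrors the accepted structure
# of the group - Thecosomata (Euthecosomata = Cavolinioidea + Limacinoidea,
# plus Pseudothecosomata) sister to Gymnosomata, with three aplysiomorph/
# cephalaspidean outgroups - but the taxa, ages and branch lengths are
# synthetic stand-ins, not estimates.

#' Example 28-taxon pteropod chronogram (synthetic)
#'
#' A hand-specified dated tree with 25 ingroup taxa and 3 outgroups whose
#' clade structure supports every fossil calibration of
#' [pteropod_calibration_table()] (all true node ages sit above the
#' corresponding minima). Used as the known truth in simulation studies.
#'
#' @return a [dated_tree()] with root age 170 Ma.
#' @export
pteropod_example_tree <- function() {
  nd <- function(age, a, b) list(age = age, kids = list(a, b))
  cavolinioidea <- nd(99,
    nd(45,
      nd(20, "Diacria_trispinosa", "Diacria_major"),
      nd(25, "Cavolinia_uncinata", "Diacavolinia_longirostris")),
    nd(70,
      nd(40, "Clio_pyramidata", "Clio_cuspidata"),
      nd(55, "Cuvierina_atlantica",
        nd(35, "Creseis_virgula", "Styliola_subula"))))
  limacinoidea <- nd(90, "Heliconoides_inflatus",
    nd(75, "Limacina_helicina",
      nd(60, "Limacina_bulimoides",
        nd(40, "Limacina_trochiformis", "Limacina_lesueurii"))))
  pseudothecosomata <- nd(90,
    nd(50, "Peracle_reticulata", "Peracle_bispinosa"),
    nd(60, "Cymbulia_peronii", "Corolla_spectabilis"))
  gymnosomata <- nd(100, "Hydromyles_globulosus",
    nd(80,
      nd(50, nd(30, "Clione_limacina", "Clione_antarctica"),
        "Paedoclione_doliiformis"),
      nd(60, "Pneumoderma_violaceum",
        nd(45, "Pneumodermopsis_canephora", "Spongiobranchaea_australis"))))
  pteropoda <- nd(139,
    nd(129, nd(110, cavolinioidea, limacinoidea), pseudothecosomata),
    gymnosomata)
  root <- nd(170, "Philine_angasi",
    nd(160, "Haminoea_antillarum",
      nd(150, "Aplysia_californica", pteropoda)))
  newick <- function(x, parent_age) {
    if (is.character(x)) return(sprintf("%s:%.6f", x, parent_age))
    sprintf("(%s,%s):%.6f",
            newick(x$kids[[1]], x$age), newick(x$kids[[2]], x$age),
            parent_age - x$age)
  }
  txt <- sprintf("(%s,%s);", newick(root$kids[[1]], root$age),
                 newick(root$kids[[2]], root$age))
  dated_tree(ape::read.tree(text = txt))
}

#' Clade definitions for the example tree
#'
#' Named taxon sets resolving every calibration clade of
#' [pteropod_calibration_table()] on [pteropod_example_tree()].
#'
#' @return named list of character vectors.
#' @export
pteropod_clade_defs <- function() {
  diacria <- c("Diacria_trispinosa", "Diacria_major")
  cav_dia <- c("Cavolinia_uncinata", "Diacavolinia_longirostris")
  cavolinioidea <- c(diacria, cav_dia, "Clio_pyramidata", "Clio_cuspidata",
                     "Cuvierina_atlantica", "Creseis_virgula", "Styliola_subula")
  limacina <- c("Limacina_helicina", "Limacina_bulimoides",
                "Limacina_trochiformis", "Limacina_lesueurii")
  limacinoidea <- c("Heliconoides_inflatus", limacina)
  pseudothecosomata <- c("Peracle_reticulata", "Peracle_bispinosa",
                         "Cymbulia_peronii", "Corolla_spectabilis")
  gymnosomata <- c("Hydromyles_globulosus", "Clione_limacina",
                   "Clione_antarctica", "Paedoclione_doliiformis",
                   "Pneumoderma_violaceum", "Pneumodermopsis_canephora",
                   "Spongiobranchaea_australis")
  pteropoda <- c(cavolinioidea, limacinoidea, pseudothecosomata, gymnosomata)
  list(Diacria = diacria,
       Cavolinia_Diacavolinia = cav_dia,
       Cavolinia_Diacavolinia_Diacria = c(diacria, cav_dia),
       Cavolinioidea = cavolinioidea,
       Limacina = limacina,
       Limacinoidea = limacinoidea,
       Euthecosomata = c(cavolinioidea, limacinoidea),
       Pseudothecosomata = pseudothecosomata,
       Thecosomata = c(cavolinioidea, limacinoidea, pseudothecosomata),
       Gymnosomata = gymnosomata,
       Pteropoda = pteropoda,
       Pteropoda_Aplysia = c(pteropoda, "Aplysia_californica"))
}

#' @rdname pteropod_clade_defs
#' @export
pteropod_ingroup <- function() pteropod_clade_defs()$Pteropoda

#' @rdname pteropod_clade_defs
#' @export
pteropod_outgroup <- function() c("Philine_angasi", "Haminoea_antillarum",
                                  "Aplysia_californica")
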