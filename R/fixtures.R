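#' Femoral nonflying-diver class (F0D2), as published
#'
#' The 59 published femoral specimens coded nonflying / frequently diving
#' (`F0D2`) in the full femoral training dataset, ranked by global bone
#' compactness, with extinct/extant status as printed. Values are embedded
#' verbatim from the published ranking (including its occasional oddities,
#' e.g. the water opossum carrying no extant mark); 43 records are extinct
#' and 16 extant.
#'
#' @return Specimen tibble with an additional `rank` column (1 = highest Cg).
#' @export
femoral_diver_records <- function() {
  txt <- "rank|taxon_id|md_mm|cg|status
1|Serpianosaurus|4.8|0.989|extinct
2|Large_Eocene_stem_penguin|16.744|0.988|extinct
3|Maiacetus|30.43|0.985|extinct
4|Nanophoca_vitulinoides|20.3|0.973|extinct
5|Cryptoclidus|84.08|0.97|extinct
6|Champsosaurus_|7.85|0.968|extinct
7|Neusticosaurus|19.1|0.968|extinct
8|Phocanella_pumila|29.5|0.966|extinct
9|Placondontia_indet|23.38|0.959|extinct
10|Nothosaurus_102|5.168|0.955|extinct
11|Champsosaurus|12.389|0.952|extinct
12|Small_Eocene_penguin|9.457|0.942|extinct
13|Paraplacodus|9.05|0.939|extinct
14|Nothosaurus_150|8.125|0.938|extinct
15|Rhaeticosaurus|36|0.936|extinct
16|Caiman_yacare|12.623|0.929|extant
17|Basilosaurus|21.96|0.926|extinct
18|Nothosaurus_568|5.464|0.909|extinct
19|Anarosaurus|10|0.901|extinct
20|Plesiosaurus|41|0.9|extinct
21|Rodhocetus|26.863|0.893|extinct
22|Desmana_moschata|5.1|0.89|extant
23|Alligator|18|0.884|extant
24|Cricosaurus|16.265|0.874|extinct
25|Spheniscus_humboldti|8.06|0.872|extant
26|Ornithorhynchus_anatinus|5.21|0.871|extant
27|Indohyus|7.44|0.867|extinct
28|Simosaurus|22.97|0.865|extinct
29|Aptenodytes|16.395|0.864|extant
30|Placodontia_indet_1|20.97|0.859|extinct
31|Lutra_vulgaris|10.02|0.85|extant
32|Chironectes_minimus|4.78|0.849|extinct
33|Pistosaurus|27.56|0.845|extinct
34|Micropotamogale_euwenzorii|2.31|0.844|extant
35|Psephoderma|9.37|0.843|extinct
36|Metryorhynchus|27.384|0.828|extinct
37|Nothosaurus_mirabilis|16.09|0.828|extinct
38|Hippopotamus_amphibius|59.34|0.828|extant
39|Otaria_byronia|22.28|0.821|extant
40|Palaeospheniscus|8.52|0.792|extinct
41|Ichthyosaur_sp|165.44|0.776|extinct
42|Nothosaurus_mirabilis_1|21.7|0.776|extinct
43|Choeropsis_liberiensis|29.78|0.767|extant
44|Remingtonocetus|35.72|0.765|extinct
45|Simosaurus_1|22.9|0.764|extinct
46|Castor_fiber|29|0.749|extant
47|Nothosaurus_giganteus|26.819|0.738|extinct
48|Callophoca_obscura|25.86|0.733|extinct
49|Leptophoca_proxima|28.9|0.729|extinct
50|Neomys_fodiens|0.969|0.729|extant
51|Hexaprotodon_garyam|69.4|0.726|extinct
52|Hesperornis|22.914|0.725|extinct
53|Hydromys_chrysogaster|5.42|0.689|extant
54|Tapirus_terrestris|33.2|0.687|extant
55|Protochampsidae|10.17|0.673|extinct
56|Ichthyosaurus|86.48|0.659|extinct
57|Dyrosaurid|12.54|0.635|extinct
58|Phalacrocorax_harrisi|9.26|0.623|extant
59|Desmostylus_hesperus|38|0.596|extinct"
  ds <- readr::read_delim(I(txt), delim = "|", show_col_types = FALSE,
                          progress = FALSE)
  ds <- tibble::as_tibble(ds)
  ds$fly_code <- "0"
  ds$dive_code <- "2"
  ds$role <- "train"
  validate_compactness(ds)
  attr(ds, "dataset_name") <- "femoral_divers_F0D2"
  ds
}

#' Published repeated Cg measurements per taxon and bone
#'
#' Compilation of the cases in the literature where the same bone of the same
#' taxon has been measured for compactness more than once, together with the
#' published relative range of each entry. Used for the individual-variation
#' statistics; the relative range is recomputed from the raw measurements and
#' the published value retained for cross-checking.
#'
#' @return Tibble with one row per (taxon, bone) entry: `taxon`, `bone`,
#'   list-column `cg` of raw measurements, and `published_range` (percent).
#' @export
cg_variation_entries <- function() {
  e <- list(
    list("Phoca_vitrulina",         "rib",            c(0.436, 0.544),          22.0),
    list("Sphenicus_humboldti",     "rib",            c(0.908, 0.711),          24.3),
    list("Giraffa_camelopardalis",  "rib",            c(0.544, 0.553),          1.6),
    list("Metriorhynchus",          "femur",          c(0.828, 0.518),          46.1),
    list("Ceratherium_simum",       "femur",          c(0.669, 0.819, 0.827),   20.5),
    list("Mammuthus",               "femur",          c(0.846, 0.898, 0.773),   14.9),
    list("Nothosaurus_mirabilis",   "femur",          c(0.828, 0.776),          6.5),
    list("Nothosaurus",             "femur",          c(0.955, 0.938, 0.909),   4.9),
    list("Simosaurus",              "femur",          c(0.865, 0.764),          12.4),
    list("Diceros_bicornis",        "humerus",        c(0.866, 0.937),          7.9),
    list("Ceratherium_simum",       "humerus",        c(0.771, 0.870),          12.1),
    list("Dicerorhinus_sumatrensis","humerus",        c(0.941, 0.7895),         17.5),
    list("Scutellosaurus_lawleri",  "humerus",        c(0.767, 0.748, 0.898),   18.6),
    list("Dromaius_novaehollandae", "tarsometatarsus",c(0.655, 0.560),          15.6),
    list("Rhea_americana",          "femur",          c(0.656, 0.404),          47.5),
    list("Rhea_americana",          "tibia",          c(0.459, 0.644),          33.5),
    list("Rhea_americana",          "tarsometatarsus",c(0.826, 0.618),          28.2),
    list("Struthio_camelus",        "femur",          c(0.392, 0.289),          30.2),
    list("Aepyornithidae",          "femur",          c(0.512, 0.386),          28.1)
  )
  tibble::tibble(
    taxon = vapply(e, `[[`, "", 1),
    bone = vapply(e, `[[`, "", 2),
    cg = lapply(e, `[[`, 3),
    published_range = vapply(e, `[[`, 0, 4)
  )
}

#' Published spinosaurid test points
#'
#' The femoral and rib test points used for the three spinosaurid taxa, as
#' published (variant 0 of each sensitivity series).
#'
#' @return Tibble with `dataset` ("femur"/"rib"), `taxon`, `md_mm`, `cg`.
#' @export
spinosaurid_test_points <- function() {
  tibble::tribble(
    ~dataset, ~taxon,        ~md_mm, ~cg,
    "femur",  "Baryonyx",    154,    0.876,
    "femur",  "Spinosaurus", 81.52,  0.968,
    "femur",  "Suchomimus",  120.6,  0.682,
    "rib",    "Baryonyx",    42.2,   0.921,
    "rib",    "Spinosaurus", 35.10,  0.931
  )
}
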