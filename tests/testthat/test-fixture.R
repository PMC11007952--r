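# The packaged volvocine fixture: topology, ages, codings, provenance.

fx <- build_volvocine_fixture()

test_that("the fixture tree has the reported topology", {
  tr <- fx$tree
  expect_equal(ape::Ntip(tr), 31L)
  is_clade <- function(...) {
    tips <- c(...)
    mrca <- ape::getMRCA(tr, tips)
    setequal(ape::extract.clade(tr, mrca)$tip.label, tips)
  }
  # Goniaceae monophyletic
  expect_true(is_clade("Gonium_pectorale", "Astrephomene_gubernaculifera"))
  # Vitreochlamys sister to the Tetrabaenaceae
  expect_true(is_clade("Vitreochlamys_aulata", "Vitreochlamys_ordinata",
                       "Basichlamys_sacculifera",
                       "Tetrabaena_socialis_NIES571",
                       "Tetrabaena_socialis_NIES691"))
  # the Chlamydomonas clade is sister to the Goniaceae + Volvocaceae
  expect_true(is_clade("Chlamydomonas_schloesseri", "Chlamydomonas_incerta",
                       "Chlamydomonas_reinhardtii"))
  # section Volvox sister to all other Volvocaceae
  expect_true(is_clade("Volvox_globator", "Volvox_barberi"))
  volvocaceae <- volvoclock:::.fixture_volvocaceae()
  expect_true(is_clade(volvocaceae))
  # Platydorina + Colemanosphaera are sisters inside the PVC clade
  expect_true(is_clade("Platydorina_caudata",
                       "Colemanosphaera_charkowiensis"))
})

test_that("reported node ages and HPDs are carried on the right nodes", {
  expect_equal(unname(fx$ages[as.character(fx$node_of["tgv_crown"])]), 298)
  expect_equal(unname(fx$ages[as.character(fx$node_of["vitreo_split"])]),
               267)
  expect_equal(unname(fx$ages[as.character(fx$node_of["chlam_split"])]),
               274)
  expect_equal(unname(fx$ages[as.character(fx$node_of["tet_crown"])]), 89)
  expect_equal(unname(fx$ages[as.character(fx$node_of["gonvolv_crown"])]),
               247)
  expect_equal(unname(fx$ages[as.character(fx$node_of["volvocaceae_crown"])]),
               228)
  expect_equal(unname(fx$ages[as.character(fx$node_of["goniaceae_crown"])]),
               220)
  expect_equal(unname(fx$ages[as.character(fx$node_of["tsoc_split"])]), 51)
  expect_equal(fx$hpd[[as.character(fx$node_of["tgv_crown"])]], c(237, 349))
})

test_that("trait codings follow the genus-level statements", {
  tm <- as.data.frame(fx$traits)
  expect_equal(tm["Yamagishiella_unicocca", "gametes3"], "isogamy")
  expect_equal(tm["Eudorina_elegans", "gametes3"], "anisogamy")
  expect_equal(tm["Volvox_carteri", "gametes3"], "oogamy")
  expect_equal(tm["Pandorina_morum", "gametes2"], "isogamy")
  expect_equal(tm["Chlamydomonas_reinhardtii", "cellularity"],
               "unicellular")
  expect_equal(tm["Gonium_pectorale", "inversion3"], "partial")
  expect_equal(tm["Volvox_globator", "inversion3"], "complete")
  expect_equal(tm["Astrephomene_gubernaculifera", "kirk09_somatic_cells"],
               "present")
  expect_equal(tm["Pleodorina_japonica", "kirk10_germ_cells"], "absent")
  # sexually uncharacterized taxa are coded missing for sexual traits
  expect_equal(tm["Pleodorina_thompsonii", "gametes3"], "?")
  expect_equal(tm["Vitreochlamys_ordinata", "meiotic_hatching"], "?")
})

test_that("every non-missing coding is traceable in the provenance table", {
  tm <- as.data.frame(fx$traits)
  prov <- fx$provenance
  for (ch in names(tm)) {
    rows <- prov[prov$character == ch, ]
    expect_gt(nrow(rows), 0L)
    covered <- unlist(strsplit(rows$taxa, ";"))
    coded <- rownames(tm)[tm[[ch]] != "?"]
    expect_true(all(coded %in% covered), info = ch)
  }
  expect_true(all(nzchar(prov$note)))
})

test_that("fixture files round-trip through the package readers", {
  d <- tempfile()
  build_volvocine_fixture(d)
  tr <- read_newick(file.path(d, "volvocine_tree.nwk"),
                    length_kind = "time")
  expect_equal(sort(tr$tip.label), sort(fx$tree$tip.label))
  ann <- read_annotated_tree(file.path(d, "volvocine_chronogram.nex"))
  tgv <- ape::getMRCA(ann$tree, c("Tetrabaena_socialis_NIES571",
                                  "Volvox_carteri"))
  got <- ann$annotations[[as.character(tgv)]]
  expect_equal(unname(got["age"]), 298)
  expect_equal(unname(got[c("hpd_lower", "hpd_upper")]), c(237, 349))
  tm <- read_traits(file.path(d, "volvocine_traits.tsv"),
                    file.path(d, "volvocine_traits.tsv.states"))
  expect_equal(as.data.frame(tm), as.data.frame(fx$traits))
  cal <- read_calibrations(file.path(d, "archaeplastida_calibrations.tsv"))
  expect_equal(nrow(cal), 14L)
})

test_that("fixture origin counts reproduce the study's numbers", {
  # two origins of multicellularity; both realizable as gains
  fc <- fitch_count(fx$tree, fx$traits, character = "cellularity")
  expect_equal(fc$count, 2L)
  expect_equal(count_origins(fx$tree, fx$traits, derived = "multicellular",
                             character = "cellularity"), 2L)
  # three origins of anisogamy under both codings
  expect_equal(count_origins(fx$tree, fx$traits, derived = "anisogamy",
                             character = "gametes2"), 3L)
  expect_equal(count_origins(fx$tree, fx$traits,
                             derived = c("anisogamy", "oogamy"),
                             character = "gametes3"), 3L)
  # two losses of full meiotic hatching under the irreversible treatment
  st <- c("full", "reduced")
  loss_only <- matrix(c(0, Inf, 1, 0), 2, 2, dimnames = list(st, st))
  x <- volvoclock:::.trait_column(fx$traits, "meiotic_hatching", fx$tree)
  sk <- sankoff_cost(fx$tree, x, loss_only, root_state = "full",
                     derived = "reduced")
  expect_equal(sk$cost, 2)
  expect_equal(sk$min_gains, 2)
  # somatic differentiation: at least four independent gains
  expect_gte(count_origins(fx$tree, fx$traits, derived = "present",
                           character = "kirk09_somatic_cells"), 4L)
})
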