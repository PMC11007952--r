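# Tree, trait, calibration and sequence I/O.

test_that("Newick reading validates and round-trips", {
  tr <- read_newick("((A:1,B:1):1,C:2);")
  expect_equal(ape::Ntip(tr), 3L)
  expect_equal(sum(tr$edge[, 1L] == 4L), 2L)  # root has two children

  rt <- read_newick(write_newick(tr))
  expect_equal(rt$tip.label, tr$tip.label)
  expect_equal(rt$edge.length, tr$edge.length)

  # round trip over random 20-tip synthetic trees at 1e-9
  for (s in 1:5) {
    tr <- sim_bd_tree(20, lambda = 0.05, mu = 0.01, seed = s)
    rt <- read_newick(write_newick(tr), length_kind = "time")
    expect_equal(ape::Ntip(rt), 20L)
    d1 <- ape::cophenetic.phylo(tr)
    d2 <- ape::cophenetic.phylo(rt)[rownames(d1), colnames(d1)]
    expect_lt(max(abs(d1 - d2)), 1e-9)
  }
})

test_that("malformed Newick is rejected with a character offset", {
  expect_error(read_newick("((A:1,B:1):1,C:2;"), "character")
  expect_error(read_newick("((A,B),A);"), "duplicate")
  expect_error(read_newick("((A,B),(C,D),E);"), "polytomy")
  expect_silent(read_newick("((A:1,B:1):1,(C:1,D:1):1,E:1);",
                            allow_polytomy = TRUE))
})

test_that("annotated NEXUS trees carry and recover node annotations", {
  tr <- read_newick("((A:100,B:100):198,C:298);", length_kind = "time")
  root <- 4L
  ann <- list(`4` = c(age = 298, hpd_lower = 237, hpd_upper = 349))
  txt <- write_annotated_tree(tr, ann)
  expect_match(txt, "age=298")
  expect_match(txt, "hpd_lower=237")
  expect_match(txt, "hpd_upper=349")

  # empty annotations give a plain Newick body
  plain <- write_annotated_tree(tr, list())
  expect_false(grepl("\\[&", sub(".*TREE1 = \\[&R\\]", "", plain)))

  # round trip recovers annotation values exactly
  f <- tempfile(fileext = ".nex")
  ann2 <- list(`4` = c(age = 298.25, hpd_lower = 237.5, hpd_upper = 349.125),
               `5` = c(age = 100.5, hpd_lower = 80.25, hpd_upper = 120.75))
  write_annotated_tree(tr, ann2, file = f)
  back <- read_annotated_tree(f)
  expect_equal(sort(back$tree$tip.label), c("A", "B", "C"))
  got_root <- back$annotations[[as.character(
    ape::getMRCA(back$tree, c("A", "C")))]]
  expect_identical(unname(got_root), unname(ann2[["4"]]))
  got_ab <- back$annotations[[as.character(
    ape::getMRCA(back$tree, c("A", "B")))]]
  expect_identical(unname(got_ab), unname(ann2[["5"]]))

  expect_error(write_annotated_tree(tr, list(`99` = c(age = 1))), "unknown")
})

test_that("trait matrices read from TSV with missing data and state spaces", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("taxon\tcellularity\tgametes",
               "A\tunicellular\tisogamy",
               "B\tmulticellular\t?",
               "C\tmulticellular\tanisogamy"), f)
  tm <- read_traits(f)
  expect_s3_class(tm, "trait_matrix")
  expect_equal(dim(tm), c(3L, 2L))
  # "?" excluded from state-space inference
  expect_equal(attr(tm, "state_spaces")$gametes, c("anisogamy", "isogamy"))
  expect_equal(tm["B", "gametes"], "?")

  # sidecar state spaces are honoured and unknown symbols rejected
  sf <- tempfile()
  writeLines(c("character\tstates",
               "cellularity\tunicellular,multicellular",
               "gametes\tisogamy,anisogamy,oogamy"), sf)
  tm2 <- read_traits(f, sf)
  expect_equal(attr(tm2, "state_spaces")$gametes,
               c("isogamy", "anisogamy", "oogamy"))
  writeLines(c("taxon\tx", "A\tbogus"), f)
  sf2 <- tempfile()
  writeLines(c("character\tstates", "x\t0,1"), sf2)
  expect_error(read_traits(f, sf2), "unknown state")
})

test_that("NEXUS character blocks read as trait matrices", {
  f <- tempfile(fileext = ".nex")
  writeLines(c("#NEXUS",
               "BEGIN DATA;",
               "DIMENSIONS NTAX=3 NCHAR=2;",
               "FORMAT DATATYPE=STANDARD MISSING=? GAP=- SYMBOLS=\"01\";",
               "MATRIX",
               "taxA 01",
               "taxB 11",
               "taxC 0?",
               ";",
               "END;"), f)
  tm <- read_traits(f)
  expect_s3_class(tm, "trait_matrix")
  expect_equal(dim(tm), c(3L, 2L))
  expect_equal(unname(unlist(tm["taxA", ])), c("0", "1"))
  expect_equal(tm["taxC", 2L], "?")
  expect_equal(attr(tm, "state_spaces")[[1L]], c("0", "1"))
})

test_that("trait matrices round-trip through write_traits", {
  fx <- build_volvocine_fixture()
  f <- tempfile(fileext = ".tsv")
  write_traits(fx$traits, f)
  back <- read_traits(f, paste0(f, ".states"))
  expect_equal(as.data.frame(back), as.data.frame(fx$traits))
  expect_equal(attr(back, "state_spaces"), attr(fx$traits, "state_spaces"))
})

test_that("printed age specifications parse under all conventions", {
  expect_equal(parse_age_spec("1047 +13/-17"),
               list(min_age = 1030, max_age = 1060))
  expect_equal(parse_age_spec("MIN: 350"),
               list(min_age = 350, max_age = NA_real_))
  expect_equal(parse_age_spec("1056-948"),
               list(min_age = 948, max_age = 1056))
  expect_equal(parse_age_spec("609 +/-5"),
               list(min_age = 604, max_age = 614))
  expect_error(parse_age_spec("oldish"), "malformed")
})

test_that("the packaged 14-row calibration table loads with min < max", {
  cal <- archaeplastida_calibrations()
  expect_equal(nrow(cal), 14L)
  expect_true(all(!is.na(cal$min_age)))
  both <- !is.na(cal$max_age)
  expect_true(all(cal$min_age[both] < cal$max_age[both]))
  # min-only rows get the 5% lower tail; two-sided rows 2.5% per side
  expect_true(all(cal$tail_low[!both] == 0.05))
  expect_true(all(cal$tail_low[both] == 0.025 & cal$tail_high[both] == 0.025))
  bang <- cal[cal$name == "Bangiomorpha", ]
  expect_equal(c(bang$min_age, bang$max_age), c(1030, 1060))
})

test_that("MRCA resolution matches the ancestor-set-intersection oracle", {
  tr <- read_newick("((A,B),C);")
  expect_equal(resolve_mrca(tr, "A", "B"), 5L)
  expect_equal(resolve_mrca(tr, "A", "C"), 4L)
  expect_error(resolve_mrca(tr, "A", "Z"), "not found")

  set.seed(42)
  big <- ape::rtree(50)
  for (i in 1:100) {
    pr <- sample(big$tip.label, 2L)
    expect_identical(resolve_mrca(big, pr[1L], pr[2L]),
                     brute_mrca(big, pr[1L], pr[2L]))
  }
})

test_that("FASTA I/O preserves names, order, case and joins wrapped lines", {
  f <- tempfile(fileext = ".fa")
  writeLines(c(">s1 description here", "ACGTac", "gtAC", ">s2", "TTTT"), f)
  seqs <- read_fasta(f)
  expect_identical(seqs, c(s1 = "ACGTacgtAC", s2 = "TTTT"))

  f2 <- tempfile(fileext = ".fa")
  write_fasta(seqs, f2, width = 4L)
  expect_identical(read_fasta(f2), seqs)

  writeLines(c(">a", "AC", ">a", "GT"), f)
  expect_error(read_fasta(f), "duplicate")
  writeLines(c("AC", "GT"), f)
  expect_error(read_fasta(f), "FASTA")
  # U -> T conversion on request
  writeLines(c(">r", "ACGU"), f)
  expect_identical(unname(read_fasta(f, to_dna = TRUE)), "ACGT")
})
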