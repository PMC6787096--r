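test_that("half-oligos are 129 nt and carry the pool primers at their ends", {
  comp <- default_components()
  oa <- design_half_oligo("ACGTACGTACGTACGTACGT", 1L, comp)
  ob <- design_half_oligo("TTTTCCCCGGGGAAAATTTT", 2L, comp)
  expect_identical(nchar(oa), 129L)
  expect_identical(nchar(ob), 129L)
  expect_true(startsWith(oa, comp$primers[["BsmBI-F"]]))
  expect_true(endsWith(oa, revcomp(comp$primers[["trc-tRNA-R"]])))
  expect_true(grepl(comp$primers[["trc-tRNA-F"]], substr(ob, 1, 31), fixed = TRUE))
  expect_true(endsWith(ob, revcomp(comp$primers[["BsmBI-R"]])))
})

test_that("half-oligo design rejects invalid guides and impossible components", {
  comp <- default_components()
  expect_error(design_half_oligo("", 1L, comp), "empty")
  expect_error(design_half_oligo("ACGTACGTACGTACGTACGN", 1L, comp), "non-ACGT")
  short <- comp
  short$trcRNA <- substr(comp$trcRNA, 1, 20)
  short$tRNA <- substr(comp$tRNA, 1, 20)
  expect_error(design_half_oligo("ACGTACGTACGTACGTACGT", 1L, short),
               "achieved 80")
})

test_that("overlap assembly reproduces the direct cassette concatenation", {
  comp <- default_components()
  g1 <- "ACGTACGTACGTACGTACGT"
  g2 <- "TTTTCCCCGGGGAAAATTTT"
  oa <- design_half_oligo(g1, 1L, comp)
  ob <- design_half_oligo(g2, 2L, comp)
  cass <- assemble_full_cassette(oa, ob)
  expect_identical(nchar(cass), 227L)
  ## independent oracle: character-by-character concatenation of components
  expected <- paste0(comp$bsmbi_adapter_5, g1, comp$trcRNA, comp$tRNA, g2,
                     comp$bsmbi_adapter_3)
  expect_identical(cass, expected)
  ## a single substitution in the junction kills the overlap
  ob_bad <- ob
  substr(ob_bad, 5, 5) <- if (substr(ob_bad, 5, 5) == "A") "C" else "A"
  expect_error(assemble_full_cassette(oa, ob_bad), "no exact overlap")
})

test_that("oligo length law holds for every guide pair", {
  comp <- default_components()
  set.seed(11)
  for (i in 1:5) {
    g1 <- random_dna(1, 20)
    g2 <- random_dna(1, 20)
    oa <- design_half_oligo(g1, 1L, comp)
    ob <- design_half_oligo(g2, 2L, comp)
    cass <- assemble_full_cassette(oa, ob)
    junction <- nchar(oa) + nchar(ob) - nchar(cass)
    expect_identical(junction, 31L)
  }
})

test_that("cross-product library enumerates pos1-major with correct categories", {
  lib <- build_cross_library(toy_pos1(), toy_pos2())
  expect_identical(nrow(lib), 6L)
  expect_identical(lib$construct_id[1:3],
                   c("gTAZ_1__gB_1", "gTAZ_1__gC_1", "gTAZ_1__Ctrl2_1"))
  cats <- table(lib$category)
  expect_identical(as.integer(cats[c("DOUBLE_KO", "SINGLE_KO_POS1",
                                     "SINGLE_KO_POS2", "CTRL_CTRL")]),
                   c(2L, 1L, 2L, 1L))
  expect_identical(sum(cats), 6L)
})

test_that("cross-product size law holds for random manifest sizes", {
  set.seed(7)
  for (k in 1:4) {
    n1 <- sample(1:5, 1)
    n2 <- sample(1:7, 1)
    p1 <- guide_manifest(paste0("a", 1:n1), rep("G1", n1), random_dna(n1, 20), 1L)
    p2 <- guide_manifest(paste0("b", 1:n2), rep("G2", n2), random_dna(n2, 20), 2L)
    expect_identical(nrow(build_cross_library(p1, p2)), n1 * n2)
  }
})

test_that("manifest validation names duplicates and rejects bad input", {
  expect_error(guide_manifest(c("g1", "g1"), c("A", "B"),
                              c("ACGTACGTACGTACGTACGT", "ACGTACGTACGTACGTACGA"),
                              1L), "g1")
  expect_error(guide_manifest("a__b", "A", "ACGTACGTACGTACGTACGT", 1L), "__")
  expect_error(guide_manifest("g1", "A", "ACGTACGTACGTACGT", 1L), "20 nt")
  expect_error(build_cross_library(toy_pos2(), toy_pos1()), "slot")
  empty <- data.frame(id = character(0), target = character(0),
                      protospacer = character(0), slot = integer(0))
  expect_error(validate_guide_manifest(empty), "empty")
})

test_that("scrambled controls are absent from the reference on both strands", {
  set.seed(3)
  ref <- random_dna(1, 1000)
  idx <- build_exclusion_index(ref, k = 20)
  ctrl <- generate_scrambled_controls(5, 20, idx, seed = 9)
  expect_identical(nrow(ctrl), 5L)
  expect_true(all(ctrl$target == "CONTROL"))
  ## brute-force substring scan over both strands
  rc <- revcomp(ref)
  for (p in ctrl$protospacer) {
    expect_false(grepl(p, ref, fixed = TRUE))
    expect_false(grepl(p, rc, fixed = TRUE))
  }
  ## determinism under a fixed seed
  again <- generate_scrambled_controls(5, 20, idx, seed = 9)
  expect_identical(ctrl, again)
  expect_identical(nrow(generate_scrambled_controls(0, 20, idx)), 0L)
})

test_that("saturated exclusion index aborts with an attempt count", {
  all2 <- build_exclusion_index(paste0(random_dna(40, 50), collapse = ""), k = 2)
  expect_length(all2, 16L)
  expect_error(generate_scrambled_controls(3, 2, all2, seed = 1,
                                           max_attempts = 64),
               "attempts")
})

test_that("internal BsmBI sites in cassettes are flagged", {
  comp <- default_components()
  clean <- cassette_sequence("ACGTACGTACGTACGTACGT", "TTTTCCCCGGGGAAAATTTT",
                             comp)
  dirty <- cassette_sequence("ACGTCGTCTCGTACGTACGT", "TTTTCCCCGGGGAAAATTTT",
                             comp)
  flags <- flag_internal_bsmbi(c(clean, dirty), comp)
  expect_identical(flags, c(FALSE, TRUE))
})

test_that("manifests and components survive file round trips", {
  m <- toy_pos2()
  tsv <- tempfile(fileext = ".tsv")
  write_guide_manifest(m, tsv)
  expect_identical(read_guide_manifest(tsv), m)
  fa <- tempfile(fileext = ".fasta")
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(stats::setNames(m$protospacer,
                                             paste0(m$id, "|", m$target))), fa)
  m2 <- read_guide_manifest(fa, slot = 2L)
  expect_identical(m2$protospacer, m$protospacer)
  expect_identical(m2$target, m$target)
  cf <- tempfile(fileext = ".fasta")
  write_components_fasta(default_components(), cf)
  expect_identical(read_components_fasta(cf), default_components())
})
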