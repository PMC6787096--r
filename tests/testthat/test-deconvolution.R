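test_that("guide keys are trimmed and truncated to 19 nt as printed", {
  comp <- default_components()
  sc <- tcgi:::mate_scaffolds(comp)
  g <- "ACGTACGTACGTACGTACGT"
  fwd <- paste0(g, substr(sc$mate1, 1, 20))
  expect_identical(extract_guide_key(fwd, 1L, sc$mate1), substr(g, 1, 19))
  ## too short after trimming
  short <- paste0("ACGTACGTAC", substr(sc$mate1, 1, 20))
  expect_identical(extract_guide_key(short, 1L, sc$mate1), NA_character_)
  ## mate 2: read is revcomp(guide + downstream tRNA context); the oracle is
  ## a hand reverse complement of the expected cassette-sense 19-mer
  g2 <- "TTTTCCCCGGGGAAAATTTC"
  read2 <- paste0(revcomp(g2), substr(sc$mate2, 1, 20))
  key2 <- extract_guide_key(read2, 2L, sc$mate2)
  expect_identical(key2, substr(g2, 2, 20))
  ## N bases never survive into a key
  readN <- paste0("N", substr(g, 2, 20), substr(sc$mate1, 1, 20))
  expect_identical(extract_guide_key(readN, 1L, sc$mate1), NA_character_)
  ## positional fallback when the scaffold anchor is absent
  expect_identical(extract_guide_key(g, 1L, sc$mate1), NA_character_)
  expect_identical(extract_guide_key(g, 1L, sc$mate1, trim = "position"),
                   substr(g, 1, 19))
})

test_that("pair counting maps, rejects and accounts for every read pair", {
  comp <- default_components()
  sc <- tcgi:::mate_scaffolds(comp)
  lib <- build_cross_library(toy_pos1(), toy_pos2())
  mk1 <- function(p) paste0(p, substr(sc$mate1, 1, 21))
  mk2 <- function(p) paste0(revcomp(p), substr(sc$mate2, 1, 21))
  p1 <- toy_pos1()$protospacer
  p2 <- toy_pos2()$protospacer
  reads1 <- c(rep(mk1(p1[1]), 3), mk1(p1[2]), "ACGT",      mk1(p1[1]))
  reads2 <- c(rep(mk2(p2[1]), 3), mk2(p2[3]), mk2(p2[1]), "TTTT")
  res <- count_constructs(reads1, reads2, lib, comp)
  expect_identical(unname(res$counts["gTAZ_1__gB_1"]), 3L)
  expect_identical(unname(res$counts["gCtrl_1__Ctrl2_1"]), 1L)
  expect_identical(res$stats$total, 6L)
  expect_identical(res$stats$mapped, 4L)
  expect_identical(res$stats$unmapped, 2L)
  expect_identical(res$stats$mapped + res$stats$unmapped +
                     res$stats$discordant, res$stats$total)
  expect_error(count_constructs(reads1[1:2], reads2, lib, comp), "unequal")
})

test_that("pairs matching guides outside the library count as discordant", {
  comp <- default_components()
  sc <- tcgi:::mate_scaffolds(comp)
  partial <- build_cross_library(toy_pos1(), toy_pos2())
  partial <- partial[partial$construct_id != "gTAZ_1__gC_1", ]
  r1 <- paste0(toy_pos1()$protospacer[1], substr(sc$mate1, 1, 21))
  r2 <- paste0(revcomp(toy_pos2()$protospacer[2]), substr(sc$mate2, 1, 21))
  res <- count_constructs(r1, r2, partial, comp)
  expect_identical(res$stats$discordant, 1L)
  expect_identical(res$stats$mapped, 0L)
  expect_true(all(res$counts == 0L))
})

test_that("colliding 19-mer keys within a slot are rejected with the collision", {
  comp <- default_components()
  p2 <- toy_pos2()
  p2$protospacer[2] <- paste0("G", substr(p2$protospacer[1], 2, 20))
  lib <- build_cross_library(toy_pos1(), p2)
  expect_error(count_constructs("ACGT", "ACGT", lib, comp), "slot 2")
})

test_that("simulated screens round-trip exactly through FASTQ and counting", {
  cfg <- screen_config(n_genes = 10L, n_controls_pos2 = 4L, depth = 2e4,
                       seed = 21L)
  sl <- simulate_library(cfg)
  sim <- simulate_screen(sl$library, cfg)
  comp <- default_components()
  dir <- tempfile()
  sheet <- emit_fastq(sim$counts[, c("T0_rep1", "T14_rep1")], sl$library, comp,
                      dir, read_len = 40, error_rate = 0, seed = 5)
  sheet$sample <- c("T0_rep1", "T14_rep1")
  res <- count_screen(sheet, sl$library, comp)
  expect_identical(unname(res$counts),
                   unname(sim$counts[, c("T0_rep1", "T14_rep1")]))
  expect_true(all(res$stats$unmapped == 0L))
})

test_that("mismatch tolerance never decreases the mapped count", {
  cfg <- screen_config(n_genes = 8L, n_controls_pos2 = 3L, depth = 5e3,
                       seed = 13L)
  sl <- simulate_library(cfg)
  sim <- simulate_screen(sl$library, cfg)
  comp <- default_components()
  dir <- tempfile()
  sheet <- emit_fastq(sim$counts[, "T0_rep1", drop = FALSE], sl$library, comp,
                      dir, read_len = 40, error_rate = 0.01, seed = 6)
  r1 <- tcgi:::read_fastq_chr(sheet$fastq1[1])
  r2 <- tcgi:::read_fastq_chr(sheet$fastq2[1])
  m0 <- count_constructs(r1, r2, sl$library, comp, tolerance = 0)
  m1 <- count_constructs(r1, r2, sl$library, comp, tolerance = 1)
  expect_gte(m1$stats$mapped, m0$stats$mapped)
  expect_gt(m1$stats$mapped, 0L)
})

test_that("replicate correlations match their textbook definitions", {
  x <- c(3, 9, 27, 81, 243)
  expect_equal(replicate_correlation(x, x), 1.0, tolerance = 1e-12)
  expect_equal(replicate_correlation(1:6, 6:1, method = "spearman"), -1.0,
               tolerance = 1e-12)
  set.seed(19)
  a <- rpois(50, 200)
  b <- rpois(50, 200)
  la <- log10(a + 1); lb <- log10(b + 1)
  brute <- sum((la - mean(la)) * (lb - mean(lb))) /
    sqrt(sum((la - mean(la))^2) * sum((lb - mean(lb))^2))
  expect_equal(replicate_correlation(a, b), brute, tolerance = 1e-12)
  expect_error(replicate_correlation(rep(1, 5), 1:5), "constant")
  expect_error(replicate_correlation(1:2, 1:2), "3")
})

test_that("count matrices survive the TSV round trip", {
  m <- matrix(1:6, 3, dimnames = list(paste0("c", 1:3), c("a", "b")))
  p <- tempfile(fileext = ".tsv")
  write_counts(m, p)
  expect_identical(read_counts(p), m)
})
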