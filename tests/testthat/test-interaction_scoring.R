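test_that("background correction subtracts the control-pair median and floors", {
  counts <- matrix(c(10, 2, 5, 7, 9, 100,
                     20, 8, 6, 7, 8, 50),
                   ncol = 2,
                   dimnames = list(c("a__x", "b__x", "c1__c1", "c2__c2",
                                     "c3__c3", "d__x"),
                                   c("s1", "s2")))
  cats <- c("DOUBLE_KO", "SINGLE_KO_POS2", "CTRL_CTRL", "CTRL_CTRL",
            "CTRL_CTRL", "DOUBLE_KO")
  out <- background_correct(counts, cats)
  ## sample 1 control counts {5,7,9} -> subtract 7, floor at 0
  expect_identical(unname(out[, "s1"]), c(3, 0, 93))
  ## sample 2 control counts {6,7,8} -> subtract 7
  expect_identical(unname(out[, "s2"]), c(13, 1, 43))
  expect_false(any(grepl("^c[123]__", rownames(out))))
  ## all-zero control pairs leave the matrix unchanged bar row removal
  counts0 <- counts
  counts0[3:5, ] <- 0
  expect_identical(background_correct(counts0, cats),
                   counts0[-(3:5), ])
  expect_error(background_correct(counts, rep("DOUBLE_KO", 6)), "CTRL_CTRL")
})

test_that("background correction never increases a count", {
  set.seed(23)
  m <- matrix(rpois(60, 50), 15,
              dimnames = list(paste0("k", 1:15, "__x"), paste0("s", 1:4)))
  cats <- c(rep("CTRL_CTRL", 4), rep("DOUBLE_KO", 11))
  out <- background_correct(m, cats)
  expect_true(all(out <= m[-(1:4), ]))
  expect_true(all(out >= 0))
})

test_that("CPM filter keeps the printed boundary case and drops zero rows", {
  ## 8 x 4 toy with hand-computed CPMs (column sums 1000 -> CPM = count*1000)
  m <- matrix(c(10, 4, 0, 900, 20, 30, 5, 31,
                 4, 6, 0, 920, 19, 30, 4, 17,
                 6, 4, 0, 930, 18, 25, 5, 12,
                 4, 4, 0, 940, 17, 20, 5, 10),
              ncol = 4,
              dimnames = list(paste0("r", 1:8), paste0("s", 1:4)))
  colsums <- colSums(m)
  cpm <- sweep(m, 2, colsums, "/") * 1e6
  manual <- rowSums(cpm >= 5000) >= 2
  out <- cpm_filter(m, min_cpm = 5000, min_samples = 2)
  expect_identical(rownames(out), names(manual[manual]))
  expect_identical(attr(out, "n_removed"), sum(!manual))
  ## all-zero row is always removed
  z <- rbind(m, zero = 0)
  expect_false("zero" %in% rownames(cpm_filter(z, 5, 2)))
  expect_error(cpm_filter(m, 5, 9), "min_samples")
  ## survivor set invariant to uniform scaling of one column
  m2 <- m
  m2[, 2] <- m2[, 2] * 7
  expect_identical(rownames(cpm_filter(m2, 5000, 2)),
                   rownames(cpm_filter(m, 5000, 2)))
})

test_that("TMM factors equal the direct-formula oracle", {
  set.seed(31)
  m <- matrix(rnbinom(30 * 4, mu = exp(rnorm(30, log(200), 1)), size = 20),
              ncol = 4, dimnames = list(paste0("g", 1:30), paste0("s", 1:4)))
  m[m == 0] <- 1
  f_pkg <- tmm_factors(m, reference_column = 1)
  f_ora <- tmm_oracle(m, ref = 1)
  expect_equal(unname(f_pkg), unname(f_ora), tolerance = 1e-8)
  expect_equal(prod(f_pkg)^(1 / 4), 1, tolerance = 1e-12)
  ## identical columns give factors of exactly 1
  ident <- matrix(rep(m[, 1], 4), ncol = 4,
                  dimnames = dimnames(m))
  expect_identical(unname(tmm_factors(ident)), rep(1, 4))
  ## pure depth change: a column that is exactly twice another has no
  ## composition difference, so all factors stay at 1
  depth2 <- cbind(m[, 1], m[, 1] * 2, m[, 1], m[, 1] * 4)
  dimnames(depth2) <- dimnames(m)
  f2 <- tmm_factors(depth2, reference_column = 1)
  expect_equal(unname(f2), rep(1, 4), tolerance = 1e-6)
  ## row permutation leaves factors unchanged
  perm <- m[sample(nrow(m)), ]
  expect_equal(unname(tmm_factors(perm, reference_column = 1)),
               unname(f_pkg), tolerance = 1e-12)
  expect_error(tmm_factors(cbind(m, 0)), "zero total")
})

test_that("differential abundance is exact on degenerate and planted cases", {
  set.seed(5)
  mu <- exp(rnorm(300, log(400), 0.7))
  t0 <- sapply(1:2, function(i) rnbinom(300, mu = mu, size = 100))
  m <- cbind(t0, t0)
  dimnames(m) <- list(paste0("c", 1:300),
                      c("T0_rep1", "T0_rep2", "T14_rep1", "T14_rep2"))
  si <- data.frame(sample = colnames(m),
                   timepoint = c("T0", "T0", "T14", "T14"))
  d0 <- differential_abundance(m, si)
  expect_true(all(abs(d0$logFC) < 1e-8))
  ## planted 8-fold depletion at high counts
  planted <- 1:30
  t14 <- sapply(1:2, function(i) {
    rnbinom(300, mu = ifelse(seq_len(300) %in% planted, mu / 8, mu),
            size = 100)
  })
  m2 <- cbind(t0, t14)
  dimnames(m2) <- dimnames(m)
  d <- differential_abundance(m2, si)
  expect_equal(mean(d$logFC[planted]), -3, tolerance = 0.2)
  expect_true(all(d$fdr >= 0 & d$fdr <= 1))
  ## FDR is a monotone transform of the p-values
  expect_identical(order(d$pvalue), order(d$fdr, d$pvalue))
  bad <- m2
  bad[, 1] <- 0
  expect_error(differential_abundance(bad, si), "zero total")
  expect_error(differential_abundance(m2, data.frame(sample = "a",
                                                     timepoint = "T0")),
               "T14")
})

test_that("interaction calls reproduce the declared adjustment arithmetic", {
  hd <- hand_diff_library()
  calls <- call_interactions(hd$diff, hd$library, "TAZ")
  ## P_single = -1, P_anchor = -0.5, P_double_raw = -3
  ## -> P_double_adj = -2.5, r = 0.4 -> called
  row <- calls[calls$gene == "GENEB", ]
  expect_equal(row$p_single, -1)
  expect_equal(attr(calls, "p_anchor"), -0.5)
  expect_equal(row$p_double_adj, -2.5)
  expect_equal(row$ratio, 0.4)
  expect_true(row$called)
})

test_that("equal single and double phenotypes are never called", {
  hd <- hand_diff_library()
  hd$diff$logFC <- c(-1, -1, 0)  # P_single = P_double_adj = -1 -> r = 1
  calls <- call_interactions(hd$diff, hd$library, "TAZ")
  row <- calls[calls$gene == "GENEB", ]
  expect_equal(row$ratio, 1)
  expect_identical(row$status, "NOT_CALLED")
  ## genes at or above the threshold never appear among calls
  hd$diff$logFC <- c(-1, -2, 0)  # r = 0.5 exactly
  calls <- call_interactions(hd$diff, hd$library, "TAZ")
  expect_false(calls$called[calls$gene == "GENEB"])
})

test_that("sign policy and floor report meaningless ratios as UNDEFINED", {
  hd <- hand_diff_library()
  ## adjusted double phenotype is positive -> UNDEFINED
  hd$diff$logFC <- c(-1, 2, 0)
  expect_identical(call_interactions(hd$diff, hd$library, "TAZ")$status[1],
                   "UNDEFINED")
  ## adjusted double depletion below the floor -> UNDEFINED
  hd$diff$logFC <- c(-1, -0.3, 0)
  expect_identical(call_interactions(hd$diff, hd$library, "TAZ")$status[1],
                   "UNDEFINED")
  ## single arm shows enrichment -> UNDEFINED
  hd$diff$logFC <- c(2, -3, 0)
  expect_identical(call_interactions(hd$diff, hd$library, "TAZ")$status[1],
                   "UNDEFINED")
})

test_that("interaction calls validate anchor and arm presence", {
  hd <- hand_diff_library()
  expect_error(call_interactions(hd$diff, hd$library, "NOPE"), "anchor")
  no_anchor_ctrl <- hd$library[hd$library$construct_id != "gTAZ_1__Ctrl2_1", ]
  diff2 <- hd$diff[hd$diff$construct_id != "gTAZ_1__Ctrl2_1", ]
  expect_error(call_interactions(diff2, no_anchor_ctrl, "TAZ"),
               "anchor-control")
})

test_that("scoring is equivariant to doubling every count", {
  planted <- sprintf("GENE%04d", c(3, 11))
  cfg <- screen_config(n_genes = 30L, n_controls_pos2 = 10L, seed = 17L,
                       effect_sd = 0,
                       interaction_set = data.frame(gene = planted,
                                                    effect = -2,
                                                    single_effect = 0))
  sl <- simulate_library(cfg)
  sim <- simulate_screen(sl$library, cfg)
  s1 <- score_screen(sim$counts, sl$library, sim$sample_info, "TAZ")
  s2 <- score_screen(sim$counts * 2L, sl$library, sim$sample_info, "TAZ")
  expect_identical(s1$calls$gene[s1$calls$called],
                   s2$calls$gene[s2$calls$called])
})

test_that("planted interactions are recovered end to end", {
  planted <- sprintf("GENE%04d", c(5, 20))
  cfg <- screen_config(n_genes = 40L, n_controls_pos2 = 12L, seed = 29L,
                       effect_sd = 0,
                       interaction_set = data.frame(gene = planted,
                                                    effect = -2,
                                                    single_effect = 0))
  sl <- simulate_library(cfg)
  sim <- simulate_screen(sl$library, cfg)
  res <- score_screen(sim$counts, sl$library, sim$sample_info, "TAZ")
  expect_true(all(planted %in% res$calls$gene[res$calls$called]))
})
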