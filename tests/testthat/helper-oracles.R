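## Independent oracles and small fixture builders used across the suite.

## Direct-formula TMM estimator (Robinson & Oshlack): per-sample M/A values
## against a reference column, double rank trimming, precision-weighted mean
## of the M-values, factors rescaled to geometric mean 1. Written from the
## published formulas, independent of the package's normalization path.
tmm_oracle <- function(counts, ref, logratio_trim = 0.30, sum_trim = 0.05,
                       Acutoff = -1e10) {
  lib <- colSums(counts)
  f <- vapply(seq_len(ncol(counts)), function(k) {
    obs <- counts[, k] / lib[k]
    rf <- counts[, ref] / lib[ref]
    keep <- obs > 0 & rf > 0
    M <- log2(obs / rf)[keep]
    A <- (log2(obs) + log2(rf))[keep] / 2
    w <- (lib[k] - counts[keep, k]) / (lib[k] * counts[keep, k]) +
      (lib[ref] - counts[keep, ref]) / (lib[ref] * counts[keep, ref])
    ok <- A > Acutoff & is.finite(M) & is.finite(A)
    M <- M[ok]; A <- A[ok]; w <- w[ok]
    if (max(abs(M)) < 1e-6) return(1)
    n <- length(M)
    loL <- floor(n * logratio_trim) + 1
    hiL <- n + 1 - loL
    loS <- floor(n * sum_trim) + 1
    hiS <- n + 1 - loS
    sel <- rank(M) >= loL & rank(M) <= hiL & rank(A) >= loS & rank(A) <= hiS
    2^(sum(M[sel] / w[sel], na.rm = TRUE) / sum(1 / w[sel], na.rm = TRUE))
  }, numeric(1))
  f / exp(mean(log(f)))
}

## Affine-gap global alignment score by Gotoh dynamic programming; a gap of
## length L costs gap_open + L * gap_extend, end gaps penalized.
gotoh_score <- function(a, b, match = 2, mismatch = -3, go = 5, ge = 1) {
  a <- strsplit(a, "")[[1]]
  b <- strsplit(b, "")[[1]]
  n <- length(a); m <- length(b); NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)
  X <- matrix(NEG, n + 1, m + 1)
  Y <- matrix(NEG, n + 1, m + 1)
  M[1, 1] <- 0
  if (n >= 1) for (i in 2:(n + 1)) X[i, 1] <- -(go + (i - 1) * ge)
  if (m >= 1) for (j in 2:(m + 1)) Y[1, j] <- -(go + (j - 1) * ge)
  if (n >= 1 && m >= 1) {
    for (i in 2:(n + 1)) for (j in 2:(m + 1)) {
      s <- if (a[i - 1] == b[j - 1]) match else mismatch
      M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + s
      X[i, j] <- max(M[i - 1, j], Y[i - 1, j], X[i - 1, j] + go) - go - ge
      Y[i, j] <- max(M[i, j - 1], X[i, j - 1], Y[i, j - 1] + go) - go - ge
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

## tiny manifests reused across tests
toy_pos1 <- function() {
  guide_manifest(c("gTAZ_1", "gCtrl_1"), c("TAZ", "CONTROL"),
                 c("ACGTACGTACGTACGTACGT", "AAAACCCCAAAACCCCAAAA"), 1L)
}

toy_pos2 <- function() {
  guide_manifest(c("gB_1", "gC_1", "Ctrl2_1"), c("GENEB", "GENEC", "CONTROL"),
                 c("TTTTCCCCGGGGAAAATTTT", "GGGGTTTTAAAACCCCGGGG",
                   "CCCCAAAATTTTGGGGCCCC"), 2L)
}

## synthetic differential result + matching library for call_interactions
## arithmetic tests: logFC values are chosen by hand per arm
hand_diff_library <- function() {
  lib <- build_cross_library(
    guide_manifest(c("gTAZ_1", "gCtrl_1"), c("TAZ", "CONTROL"),
                   c("ACGTACGTACGTACGTACGT", "AAAACCCCAAAACCCCAAAA"), 1L),
    guide_manifest(c("gB_1", "Ctrl2_1"), c("GENEB", "CONTROL"),
                   c("TTTTCCCCGGGGAAAATTTT", "CCCCAAAATTTTGGGGCCCC"), 2L))
  diff <- data.frame(
    construct_id = c("gCtrl_1__gB_1", "gTAZ_1__gB_1", "gTAZ_1__Ctrl2_1"),
    logFC = c(-1, -3, -0.5),
    logCPM = 10, pvalue = 1e-4, fdr = 1e-3, significant = TRUE,
    stringsAsFactors = FALSE)
  list(diff = diff, library = lib)
}
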