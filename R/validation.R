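## Validation statistics ------------------------------------------------------

#' Percent transduction from a puromycin titration
#'
#' `100 * cells(+puromycin) / cells(-puromycin)`.
#'
#' @param n_with_puro cell count with puromycin selection.
#' @param n_without_puro cell count without selection (> 0).
#' @return percentage.
#' @export
percent_transduction <- function(n_with_puro, n_without_puro) {
  if (any(n_without_puro <= 0)) stop("zero denominator", call. = FALSE)
  if (any(n_with_puro < 0)) stop("counts must be >= 0", call. = FALSE)
  100 * n_with_puro / n_without_puro
}

#' Bliss-independence excess over a dose matrix
#'
#' Expected combined inhibition under independence is
#' `iA + iB - iA * iB` from the single-agent margins (row 1 = drug B alone,
#' column 1 = drug A alone); the excess is observed minus expected over the
#' interior cells, and the mean synergy score is the average excess in
#' percentage points.
#'
#' @param observed inhibition matrix in `[0,1]`; `[1,1]` is vehicle.
#' @param clip_negative clip small negative inhibitions (>= -0.1) to 0
#'   before checking the range (default TRUE).
#' @return list with `excess` (matrix over interior cells), `expected`
#'   (full matrix) and `mean_score` (percentage points).
#' @export
bliss_excess <- function(observed, clip_negative = TRUE) {
  obs <- as.matrix(observed)
  if (clip_negative) obs[obs < 0 & obs >= -0.1] <- 0
  if (any(obs < 0 | obs > 1)) {
    stop("inhibition values outside [0,1]", call. = FALSE)
  }
  if (nrow(obs) < 2L || ncol(obs) < 2L) {
    stop("need single-agent margins plus at least one combination cell",
         call. = FALSE)
  }
  iA <- obs[, 1L]  # drug A alone (varying dose down the rows)
  iB <- obs[1L, ]  # drug B alone (across the columns)
  expected <- outer(iA, iB, function(a, b) a + b - a * b)
  excess <- (obs - expected)[-1L, -1L, drop = FALSE]
  list(excess = excess, expected = expected,
       mean_score = mean(excess) * 100)
}

#' Relative proliferation fold change against a reference line
#'
#' `(T14/T0) / (ref_T14/ref_T0)`; vectors (e.g. triplicates) are handled
#' elementwise.
#'
#' @param cellline_T0,cellline_T14 counts for the line of interest.
#' @param reference_T0,reference_T14 counts for the reference (control)
#'   line.
#' @return fold-change ratio(s).
#' @export
relative_foldchange <- function(cellline_T0, cellline_T14,
                                reference_T0, reference_T14) {
  vals <- c(cellline_T0, cellline_T14, reference_T0, reference_T14)
  if (any(vals <= 0)) stop("all counts must be > 0", call. = FALSE)
  (cellline_T14 / cellline_T0) / (reference_T14 / reference_T0)
}

#' Validation accuracy
#'
#' `100 * n_confirmed / n_tested`, reported to one decimal.
#'
#' @param n_confirmed genes confirmed by individual validation.
#' @param n_tested genes tested (> 0).
#' @return percentage rounded to one decimal.
#' @export
validation_accuracy <- function(n_confirmed, n_tested) {
  if (n_tested <= 0) stop("n_tested must be > 0", call. = FALSE)
  if (n_confirmed < 0 || n_confirmed > n_tested) {
    stop("need 0 <= n_confirmed <= n_tested", call. = FALSE)
  }
  round(100 * n_confirmed / n_tested, 1L)
}
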