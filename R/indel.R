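## Amplicon indel quantification ---------------------------------------------
##
## Global affine-gap alignment of each amplicon read against the wild-type
## window, per-read classification of the edit overlapping the cut-site
## window, and the cleavage rate over aligned reads.

#' Globally align amplicon reads to a reference window
#'
#' Needleman-Wunsch alignment with affine gap penalties (defaults: match
#' +2, mismatch -3, gap open -5, gap extend -1 per base). Reads whose
#' percent identity over the alignment falls below `min_identity` are
#' classified `UNALIGNED`.
#'
#' @param reads character vector (or `DNAStringSet`) of read sequences.
#' @param reference wild-type amplicon window (DNA string).
#' @param match,mismatch substitution scores.
#' @param gap_open,gap_extend gap penalties (positive numbers; a gap of
#'   length L costs `gap_open + L * gap_extend`).
#' @param min_identity identity floor in `[0,1]` below which a read is
#'   `UNALIGNED` (default 0.6).
#' @return data frame: `read_id`, `aligned_read`, `aligned_ref`, `score`,
#'   `identity`, `aligned` (logical).
#' @export
align_to_amplicon <- function(reads, reference, match = 2, mismatch = -3,
                              gap_open = 5, gap_extend = 1,
                              min_identity = 0.6) {
  if (length(reads) == 0L) stop("no reads given", call. = FALSE)
  if (!nzchar(reference)) stop("empty reference", call. = FALSE)
  reads <- as.character(reads)
  if (is.null(names(reads))) names(reads) <- paste0("read", seq_along(reads))
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                  mismatch = mismatch,
                                                  baseOnly = TRUE)
  aln <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAStringSet(reads),
    subject = Biostrings::DNAString(reference),
    type = "global", substitutionMatrix = mat,
    gapOpening = gap_open, gapExtension = gap_extend)
  pid <- Biostrings::pid(aln, type = "PID1") / 100
  data.frame(read_id = names(reads),
             aligned_read = as.character(Biostrings::alignedPattern(aln)),
             aligned_ref = as.character(Biostrings::alignedSubject(aln)),
             score = Biostrings::score(aln),
             identity = pid,
             aligned = pid >= min_identity,
             stringsAsFactors = FALSE, row.names = NULL)
}

## classify one aligned read/ref pair; cut_site is 0-based on the reference
classify_one <- function(aligned_read, aligned_ref, cut_site, window) {
  r <- strsplit(aligned_read, "", fixed = TRUE)[[1L]]
  s <- strsplit(aligned_ref, "", fixed = TRUE)[[1L]]
  refpos <- cumsum(s != "-")       # 1-based ref coord consumed up to column
  lo <- cut_site - window
  hi <- cut_site + window
  events <- list()
  runs <- function(x) {
    r <- rle(x)
    ends <- cumsum(r$lengths)
    data.frame(start = ends - r$lengths + 1L, end = ends, val = r$values)
  }
  del <- runs(r == "-")
  for (k in which(del$val)) {
    a <- refpos[del$start[k]] - 1L   # 0-based first deleted base
    b <- refpos[del$end[k]] - 1L     # 0-based last deleted base
    if (a <= hi && b >= lo) {
      events[[length(events) + 1L]] <-
        list(class = "DELETION", length = del$end[k] - del$start[k] + 1L,
             start = a, end = b)
    }
  }
  ins <- runs(s == "-")
  for (k in which(ins$val)) {
    q <- if (ins$start[k] == 1L) 0L else refpos[ins$start[k] - 1L]  # 0-based point
    if (q >= lo && q <= hi) {
      events[[length(events) + 1L]] <-
        list(class = "INSERTION", length = ins$end[k] - ins$start[k] + 1L,
             start = q, end = q)
    }
  }
  if (length(events)) {
    lens <- vapply(events, `[[`, numeric(1), "length")
    ev <- events[[which.max(lens)]]
    return(data.frame(class = ev$class, length = as.integer(ev$length),
                      start = ev$start, end = ev$end,
                      stringsAsFactors = FALSE))
  }
  sub <- which(r != s & r != "-" & s != "-")
  sub0 <- refpos[sub] - 1L
  in_win <- sub0 >= lo & sub0 <= hi
  if (any(in_win)) {
    return(data.frame(class = "SUBSTITUTION", length = sum(in_win),
                      start = min(sub0[in_win]), end = max(sub0[in_win]),
                      stringsAsFactors = FALSE))
  }
  data.frame(class = "WT", length = 0L, start = NA_integer_,
             end = NA_integer_, stringsAsFactors = FALSE)
}

#' Classify edits from amplicon alignments
#'
#' Indels overlapping the window `[cut_site - w, cut_site + w]` (0-based
#' reference coordinates) are called `DELETION`/`INSERTION` with the largest
#' event winning; substitutions inside the window with no windowed indel
#' give `SUBSTITUTION`; everything else (including events outside the
#' window) is `WT`. Unaligned reads keep class `UNALIGNED`.
#'
#' @param alignments data frame from [align_to_amplicon()].
#' @param cut_site 0-based cut position on the reference.
#' @param window halfwidth of the edit-calling window in nt (default 10).
#' @return data frame: `read_id`, `class`, `length`, `start`, `end`.
#' @export
classify_edits <- function(alignments, cut_site, window = 10L) {
  out <- lapply(seq_len(nrow(alignments)), function(i) {
    if (!alignments$aligned[i]) {
      return(data.frame(class = "UNALIGNED", length = NA_integer_,
                        start = NA_integer_, end = NA_integer_,
                        stringsAsFactors = FALSE))
    }
    classify_one(alignments$aligned_read[i], alignments$aligned_ref[i],
                 cut_site, window)
  })
  cbind(read_id = alignments$read_id, do.call(rbind, out))
}

#' Cleavage rate from per-read edit calls
#'
#' Rate = edited / aligned reads, where edited means `DELETION`,
#' `INSERTION` or (by default) `SUBSTITUTION`; `UNALIGNED` reads are
#' excluded from the denominator and reported separately.
#'
#' @param calls data frame from [classify_edits()] (needs a `class` column).
#' @param include_substitutions count substitutions as cleavage (default
#'   TRUE).
#' @return list with `rate`, `n_aligned`, `n_unaligned` and `class_counts`.
#' @export
cleavage_rate <- function(calls, include_substitutions = TRUE) {
  cls <- calls$class
  n_unaligned <- sum(cls == "UNALIGNED")
  aligned <- cls[cls != "UNALIGNED"]
  if (!length(aligned)) stop("no aligned reads", call. = FALSE)
  edited_classes <- c("DELETION", "INSERTION",
                      if (include_substitutions) "SUBSTITUTION")
  rate <- mean(aligned %in% edited_classes)
  list(rate = rate, n_aligned = length(aligned), n_unaligned = n_unaligned,
       class_counts = table(factor(aligned, levels = c("WT", "DELETION",
                                                       "INSERTION",
                                                       "SUBSTITUTION"))))
}
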