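## Paired-read deconvolution to construct counts -----------------------------
##
## Reads are trimmed of scaffold sequence, truncated to a 19-nt key from the
## guide-proximal end (mate-2 keys reverse-complemented into cassette sense)
## and matched by exact lookup against the library's slot-wise 19-mer keys.

#' 19-nt lookup keys for a guide manifest
#'
#' Slot-1 guides are read from their 5' end, so their key is the first 19 nt
#' of the protospacer; slot-2 guides are read back from their 3' end, so
#' their key is the last 19 nt.
#'
#' @param protospacer protospacer sequences.
#' @param slot 1 or 2.
#' @return character vector of 19-mer keys.
#' @export
guide_key <- function(protospacer, slot) {
  n <- nchar(protospacer)
  slot <- rep_len(slot, length(protospacer))
  ifelse(slot == 1L, substr(protospacer, 1L, 19L),
         substr(protospacer, n - 18L, n))
}

#' Extract 19-nt guide keys from reads
#'
#' The scaffold context downstream of the guide is located by exact match of
#' its leading `anchor_len` bases; everything from the scaffold on is
#' trimmed, the remainder is truncated to 19 nt from the guide-proximal
#' (5') end, and mate-2 keys are reverse-complemented into cassette sense.
#' Reads with fewer than 19 usable bases, or (under `trim = "scaffold"`)
#' without a scaffold hit, are rejected (`NA`).
#'
#' @param reads character vector of read sequences.
#' @param mate 1 or 2.
#' @param scaffold scaffold context in read orientation (see
#'   `mate_scaffolds()`): trcRNA for mate 1, revcomp(tRNA) for mate 2.
#' @param trim `"scaffold"` (reject reads without a scaffold hit) or
#'   `"position"` (fall back to a fixed-offset 19-mer).
#' @param offset 0-based guide start used by positional trimming.
#' @param anchor_len scaffold bases used for the exact match.
#' @return character vector of keys in cassette sense; `NA` = rejected.
#' @export
extract_guide_key <- function(reads, mate, scaffold,
                              trim = c("scaffold", "position"),
                              offset = 0L, anchor_len = 12L) {
  trim <- match.arg(trim)
  if (!mate %in% c(1L, 2L)) stop("mate must be 1 or 2", call. = FALSE)
  if (length(reads) == 0L) return(character(0))
  anchor <- substr(scaffold, 1L, anchor_len)
  hit <- regexpr(anchor, reads, fixed = TRUE)
  glen <- ifelse(hit > 0L, hit - 1L, NA_integer_)
  ## the guide region precedes the scaffold; truncate to 19 nt counted from
  ## the guide-proximal (read 5') end, so a 20-nt guide keeps bases 1..19
  key <- ifelse(!is.na(glen) & glen >= 19L,
                substr(reads, 1L, 19L), NA_character_)
  if (trim == "position") {
    fallback <- substr(reads, offset + 1L, offset + 19L)
    use_fb <- is.na(key) & nchar(fallback) == 19L
    key[use_fb] <- fallback[use_fb]
  }
  if (mate == 2L) {
    ok <- !is.na(key)
    key[ok] <- revcomp(key[ok])
  }
  key[!is.na(key) & grepl("[^ACGT]", key)] <- NA_character_
  key
}

read_fastq_chr <- function(path) {
  as.character(Biostrings::readDNAStringSet(path, format = "fastq"))
}

hamming1_lookup <- function(keys, table) {
  idx <- match(keys, table)
  todo <- which(is.na(idx) & !is.na(keys))
  if (!length(todo)) return(idx)
  uq <- unique(keys[todo])
  bases <- c("A", "C", "G", "T")
  resolve <- vapply(uq, function(k) {
    ch <- strsplit(k, "", fixed = TRUE)[[1L]]
    hitlist <- integer(0)
    for (p in seq_along(ch)) {
      for (b in bases[bases != ch[p]]) {
        v <- ch; v[p] <- b
        h <- match(paste0(v, collapse = ""), table)
        if (!is.na(h)) hitlist <- c(hitlist, h)
      }
    }
    hitlist <- unique(hitlist)
    if (length(hitlist) == 1L) hitlist else NA_integer_
  }, integer(1))
  idx[todo] <- resolve[match(keys[todo], uq)]
  idx
}

#' Count constructs from paired reads of one sample
#'
#' A read pair increments construct `(g1, g2)` iff its mate-1 key matches a
#' slot-1 guide and its mate-2 key a slot-2 guide (exact by default, with an
#' optional 1-mismatch expansion) and the combination exists in the library;
#' pairs whose two keys match guides that never co-occur in a library
#' construct are counted discordant.
#'
#' @param reads1,reads2 character vectors of mate sequences (record-aligned).
#' @param library construct library data frame.
#' @param components `oligo_components` (provides the scaffold contexts).
#' @param tolerance allowed mismatches per key, 0 (default) or 1.
#' @param ... passed to [extract_guide_key()].
#' @return list with `counts` (named integer vector over library constructs)
#'   and `stats` (`total`, `mapped`, `unmapped`, `discordant`).
#' @export
count_constructs <- function(reads1, reads2, library, components,
                             tolerance = 0L, ...) {
  if (length(reads1) != length(reads2)) {
    stop("mate files have unequal record counts", call. = FALSE)
  }
  g1 <- unique(library[, c("guide1_id", "protospacer1")])
  g2 <- unique(library[, c("guide2_id", "protospacer2")])
  key1 <- guide_key(g1$protospacer1, 1L)
  key2 <- guide_key(g2$protospacer2, 2L)
  for (kk in list(list(key1, "slot 1"), list(key2, "slot 2"))) {
    dup <- unique(kk[[1]][duplicated(kk[[1]])])
    if (length(dup)) {
      stop(sprintf("duplicate 19-mer keys within %s: %s", kk[[2]],
                   paste(utils::head(dup, 3L), collapse = ", ")), call. = FALSE)
    }
  }
  sc <- mate_scaffolds(components)
  k1 <- extract_guide_key(reads1, 1L, sc$mate1, ...)
  k2 <- extract_guide_key(reads2, 2L, sc$mate2, ...)
  lookup <- if (tolerance >= 1L) hamming1_lookup else match
  i1 <- lookup(k1, key1)
  i2 <- lookup(k2, key2)
  both <- !is.na(i1) & !is.na(i2)
  cid <- paste0(g1$guide1_id[i1[both]], CONSTRUCT_SEP, g2$guide2_id[i2[both]])
  pos <- match(cid, library$construct_id)
  mapped_pos <- pos[!is.na(pos)]
  counts <- tabulate(mapped_pos, nbins = nrow(library))
  names(counts) <- library$construct_id
  n_total <- length(reads1)
  n_mapped <- length(mapped_pos)
  n_discordant <- sum(is.na(pos))
  list(counts = counts,
       stats = data.frame(total = n_total, mapped = n_mapped,
                          unmapped = n_total - n_mapped - n_discordant,
                          discordant = n_discordant))
}

#' Count a whole screen from a sample sheet
#'
#' @param sample_sheet data frame with `sample`, `fastq1`, `fastq2` (paths).
#' @param library construct library data frame.
#' @param components `oligo_components`.
#' @param ... passed to [count_constructs()].
#' @return list with `counts` (constructs x samples integer matrix) and
#'   `stats` (per-sample mapping totals).
#' @export
count_screen <- function(sample_sheet, library, components, ...) {
  res <- lapply(seq_len(nrow(sample_sheet)), function(i) {
    count_constructs(read_fastq_chr(sample_sheet$fastq1[i]),
                     read_fastq_chr(sample_sheet$fastq2[i]),
                     library, components, ...)
  })
  counts <- do.call(cbind, lapply(res, `[[`, "counts"))
  colnames(counts) <- sample_sheet$sample
  stats <- do.call(rbind, lapply(res, `[[`, "stats"))
  stats <- cbind(sample = sample_sheet$sample, stats)
  rownames(stats) <- NULL
  list(counts = counts, stats = stats)
}

#' Replicate correlation
#'
#' `pearson-log10` correlates `log10(x + pseudocount)`; `spearman` is
#' rank-based on the raw counts.
#'
#' @param a,b equal-length count vectors (length >= 3).
#' @param method `"pearson-log10"` or `"spearman"`.
#' @param pseudocount added before the log10 transform.
#' @return correlation coefficient in `[-1, 1]`.
#' @export
replicate_correlation <- function(a, b, method = c("pearson-log10", "spearman"),
                                  pseudocount = 1) {
  method <- match.arg(method)
  if (length(a) != length(b)) stop("unequal lengths", call. = FALSE)
  if (length(a) < 3L) stop("need at least 3 observations", call. = FALSE)
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop("correlation undefined for a constant vector", call. = FALSE)
  }
  if (method == "pearson-log10") {
    stats::cor(log10(a + pseudocount), log10(b + pseudocount),
               method = "pearson")
  } else {
    stats::cor(a, b, method = "spearman")
  }
}

#' Write / read a construct count matrix as TSV
#'
#' @param counts integer matrix (constructs x samples).
#' @param path TSV file.
#' @return `path` (write) or the matrix (read).
#' @export
write_counts <- function(counts, path) {
  df <- data.frame(construct_id = rownames(counts), counts,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_counts
#' @export
read_counts <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  storage.mode(m) <- "integer"
  m
}
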