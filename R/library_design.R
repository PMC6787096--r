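## Guide manifests and the anchor x genome cross-product library -------------

CONTROL_TOKEN <- "CONTROL"
CONSTRUCT_SEP <- "__"

#' Construct a guide manifest
#'
#' A manifest is a plain data frame with one row per guide and columns
#' `id`, `target` (gene symbol or the reserved token `CONTROL`),
#' `protospacer` (20-nt, A/C/G/T) and `slot` (1 or 2).
#'
#' @param id guide identifiers (unique, must not contain `__`).
#' @param target gene symbols or `"CONTROL"`.
#' @param protospacer 20-nt protospacer sequences.
#' @param slot cassette position, 1 or 2.
#' @return validated guide manifest data frame.
#' @export
guide_manifest <- function(id, target, protospacer, slot) {
  m <- data.frame(id = as.character(id), target = as.character(target),
                  protospacer = toupper(as.character(protospacer)),
                  slot = as.integer(slot), stringsAsFactors = FALSE)
  validate_guide_manifest(m)
  m
}

#' Validate a guide manifest
#'
#' @param m candidate manifest data frame.
#' @param protospacer_len required protospacer length (default 20).
#' @return the manifest, invisibly, or an error.
#' @export
validate_guide_manifest <- function(m, protospacer_len = 20L) {
  need <- c("id", "target", "protospacer", "slot")
  if (!all(need %in% names(m))) {
    stop("manifest needs columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  if (nrow(m) == 0L) stop("empty guide manifest", call. = FALSE)
  dup <- m$id[duplicated(m$id)]
  if (length(dup)) {
    stop("duplicate guide id(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  if (any(grepl(CONSTRUCT_SEP, m$id, fixed = TRUE))) {
    stop(sprintf("guide ids may not contain '%s'", CONSTRUCT_SEP), call. = FALSE)
  }
  assert_dna(m$protospacer, "protospacer")
  if (any(nchar(m$protospacer) != protospacer_len)) {
    stop(sprintf("all protospacers must be %d nt", protospacer_len),
         call. = FALSE)
  }
  if (!all(m$slot %in% c(1L, 2L))) stop("slot must be 1 or 2", call. = FALSE)
  invisible(m)
}

#' Read a guide manifest from TSV or FASTA
#'
#' TSV files must carry the manifest columns; FASTA headers are parsed as
#' `id|target` (target defaults to the id's prefix before the first `_` when
#' no `|` is present) and `slot` must then be supplied.
#'
#' @param path input file (`.tsv`/`.txt` or `.fa`/`.fasta`).
#' @param slot slot to assign when reading FASTA.
#' @return guide manifest data frame.
#' @export
read_guide_manifest <- function(path, slot = NULL) {
  if (grepl("\\.(fa|fasta)(\\.gz)?$", path, ignore.case = TRUE)) {
    if (is.null(slot)) stop("slot required when reading FASTA", call. = FALSE)
    ss <- Biostrings::readDNAStringSet(path)
    hdr <- names(ss)
    id <- sub("\\|.*$", "", hdr)
    target <- ifelse(grepl("|", hdr, fixed = TRUE),
                     sub("^[^|]*\\|", "", hdr),
                     sub("_.*$", "", hdr))
    m <- guide_manifest(id, target, as.character(ss), slot)
  } else {
    m <- utils::read.delim(path, stringsAsFactors = FALSE)
    m <- guide_manifest(m$id, m$target, m$protospacer, m$slot)
  }
  m
}

#' Write a guide manifest to TSV
#'
#' @param m guide manifest.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_guide_manifest <- function(m, path) {
  utils::write.table(m, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

construct_category <- function(target1, target2) {
  c1 <- target1 == CONTROL_TOKEN
  c2 <- target2 == CONTROL_TOKEN
  ifelse(c1 & c2, "CTRL_CTRL",
         ifelse(c1, "SINGLE_KO_POS2",
                ifelse(c2, "SINGLE_KO_POS1", "DOUBLE_KO")))
}

#' Build the position-1 x position-2 cross-product library
#'
#' Every slot-1 guide is paired with every slot-2 guide, in slot-1-major
#' order, giving `|pos1| * |pos2|` dual constructs. Categories: `DOUBLE_KO`
#' (two gene-targeting guides), `SINGLE_KO_POS1`/`SINGLE_KO_POS2` (one
#' control guide; the suffix names the slot carrying the *targeting* guide is
#' the other one, i.e. `SINGLE_KO_POS2` means the slot-1 guide is a control),
#' and `CTRL_CTRL` (both controls).
#'
#' @param pos1 slot-1 guide manifest.
#' @param pos2 slot-2 guide manifest.
#' @param components optional `oligo_components`; when given, the assembled
#'   cassette sequence is included and internal BsmBI sites flagged.
#' @return data frame with one row per construct: `construct_id`,
#'   `guide1_id`, `guide2_id`, `target1`, `target2`, `protospacer1`,
#'   `protospacer2`, `category` (+ `cassette`, `internal_bsmbi`).
#' @export
build_cross_library <- function(pos1, pos2, components = NULL) {
  validate_guide_manifest(pos1)
  validate_guide_manifest(pos2)
  if (!all(pos1$slot == 1L)) stop("pos1 guides must have slot = 1", call. = FALSE)
  if (!all(pos2$slot == 2L)) stop("pos2 guides must have slot = 2", call. = FALSE)
  i1 <- rep(seq_len(nrow(pos1)), each = nrow(pos2))
  i2 <- rep(seq_len(nrow(pos2)), times = nrow(pos1))
  lib <- data.frame(
    construct_id = paste0(pos1$id[i1], CONSTRUCT_SEP, pos2$id[i2]),
    guide1_id = pos1$id[i1], guide2_id = pos2$id[i2],
    target1 = pos1$target[i1], target2 = pos2$target[i2],
    protospacer1 = pos1$protospacer[i1], protospacer2 = pos2$protospacer[i2],
    stringsAsFactors = FALSE
  )
  lib$category <- construct_category(lib$target1, lib$target2)
  if (!is.null(components)) {
    lib$cassette <- cassette_sequence(lib$protospacer1, lib$protospacer2,
                                      components)
    lib$internal_bsmbi <- flag_internal_bsmbi(lib$cassette, components)
  }
  lib
}

#' Write a library manifest to TSV
#'
#' @param library construct library data frame from [build_cross_library()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_library_manifest <- function(library, path) {
  utils::write.table(library, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a library manifest from TSV
#'
#' @param path TSV written by [write_library_manifest()].
#' @return construct library data frame.
#' @export
read_library_manifest <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Write half-oligo pools as FASTA
#'
#' @param oligos named character vector from [design_half_oligos()].
#' @param path output FASTA.
#' @return `path`, invisibly.
#' @export
write_half_oligos_fasta <- function(oligos, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(oligos), path)
  invisible(path)
}

#' Build an exclusion k-mer index from reference sequences
#'
#' Enumerates every k-mer of the reference (both strands) for exact
#' absence checks on candidate non-targeting controls.
#'
#' @param reference character vector of reference sequences, a
#'   `DNAStringSet`, or a path to a FASTA file.
#' @param k k-mer size (= control guide length).
#' @return character vector of unique k-mers (an "exclusion index").
#' @export
build_exclusion_index <- function(reference, k) {
  if (is.character(reference) && length(reference) == 1L &&
      file.exists(reference)) {
    reference <- Biostrings::readDNAStringSet(reference)
  }
  if (methods::is(reference, "DNAStringSet")) {
    reference <- as.character(reference)
  }
  reference <- toupper(reference)
  kmers <- function(s) {
    n <- nchar(s)
    if (n < k) return(character(0))
    substring(s, seq_len(n - k + 1L), seq_len(n - k + 1L) + k - 1L)
  }
  fwd <- unlist(lapply(reference, kmers), use.names = FALSE)
  unique(c(fwd, revcomp(fwd)))
}

#' Generate scrambled non-targeting control guides
#'
#' Draws random sequences and keeps those absent (forward and reverse
#' complement) from the exclusion index, until `n` distinct controls are
#' found. Deterministic under a fixed seed.
#'
#' @param n number of controls.
#' @param length guide length in nt (default 20).
#' @param exclusion_index k-mer set from [build_exclusion_index()], or NULL
#'   to skip the genome-absence check (emits a warning).
#' @param seed RNG seed.
#' @param slot slot assigned to the controls (default 2).
#' @param max_attempts bound on candidate draws before giving up.
#' @param prefix id prefix.
#' @return guide manifest of `n` controls with `target = "CONTROL"`.
#' @export
generate_scrambled_controls <- function(n, length = 20L, exclusion_index = NULL,
                                        seed = 1L, slot = 2L,
                                        max_attempts = 1000L + 100L * n,
                                        prefix = "CTRL") {
  if (n < 0L) stop("n must be >= 0", call. = FALSE)
  if (length < 1L) stop("length must be >= 1", call. = FALSE)
  if (n == 0L) {
    return(data.frame(id = character(0), target = character(0),
                      protospacer = character(0), slot = integer(0)))
  }
  if (is.null(exclusion_index)) {
    warning("no reference given: controls are not checked for genome absence")
    exclusion_index <- character(0)
  }
  set.seed(seed)
  found <- character(0)
  attempts <- 0L
  while (length(found) < n) {
    batch <- max(2L * (n - length(found)), 32L)
    if (attempts + batch > max_attempts) batch <- max_attempts - attempts
    if (batch <= 0L) {
      stop(sprintf("could not find %d absent sequences in %d attempts (%d found)",
                   n, attempts, length(found)), call. = FALSE)
    }
    cand <- random_dna(batch, length)
    attempts <- attempts + batch
    ok <- !(cand %in% exclusion_index) & !(revcomp(cand) %in% exclusion_index)
    found <- unique(c(found, cand[ok]))
  }
  found <- found[seq_len(n)]
  guide_manifest(sprintf("%s%04d", prefix, seq_len(n)),
                 rep(CONTROL_TOKEN, n), found, rep(as.integer(slot), n))
}
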