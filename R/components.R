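## Oligo architecture -------------------------------------------------------
##
## A library member is synthesised as two 129-nt half-oligos that share a
## guide-independent junction inside the trcRNA/tRNA block and are merged by
## overlap PCR into the 227-nt cassette
##
##   [BsmBI adapter] gRNA1 [trcRNA] [tRNA] gRNA2 [BsmBI adapter]
##
## Component sequences are configuration, not constants: they are read from a
## FASTA file and the shipped defaults (see `default_components()`) are a
## synthetic reconstruction anchored on the printed amplification primers.

TARGET_HALF_OLIGO_LEN <- 129L
BSMBI_SITE <- "CGTCTC" # recognition site; GAGACG on the other strand

#' Oligo component set for the dual-guide cassette
#'
#' Bundles the guide-independent sequences of the cassette architecture:
#' the two BsmBI cloning adapters, the guide scaffold (trcRNA) and the tRNA
#' spacer, plus the four pool-amplification primers.
#'
#' @param bsmbi_adapter_5,bsmbi_adapter_3 DNA strings flanking the cassette;
#'   each must contain a BsmBI recognition site (CGTCTC or GAGACG).
#' @param trcRNA guide scaffold DNA string placed after gRNA1.
#' @param tRNA tRNA spacer DNA string placed between scaffold and gRNA2.
#' @param primers named character vector with entries `BsmBI-F`, `trc-tRNA-R`,
#'   `trc-tRNA-F`, `BsmBI-R`.
#' @return an object of class `oligo_components`.
#' @export
oligo_components <- function(bsmbi_adapter_5, trcRNA, tRNA, bsmbi_adapter_3,
                             primers) {
  seqs <- c(bsmbi_adapter_5 = bsmbi_adapter_5, trcRNA = trcRNA,
            tRNA = tRNA, bsmbi_adapter_3 = bsmbi_adapter_3)
  assert_dna(unname(seqs), "component sequence")
  need <- c("BsmBI-F", "trc-tRNA-R", "trc-tRNA-F", "BsmBI-R")
  if (!all(need %in% names(primers))) {
    stop("primers must be named: ", paste(need, collapse = ", "), call. = FALSE)
  }
  assert_dna(unname(primers[need]), "primer")
  out <- list(bsmbi_adapter_5 = unname(bsmbi_adapter_5),
              trcRNA = unname(trcRNA),
              tRNA = unname(tRNA),
              bsmbi_adapter_3 = unname(bsmbi_adapter_3),
              primers = primers[need])
  class(out) <- "oligo_components"
  out
}

#' Default (synthetic) component set
#'
#' The printed amplification primers are used verbatim; the trcRNA is the
#' canonical 76-nt S. pyogenes sgRNA scaffold; the tRNA spacer starts with the
#' 13 nt implied by the reverse primer of the first oligo pool and continues
#' with synthetic tRNA-like filler so that component lengths reproduce the
#' 129/129/227-nt oligo architecture. A copy ships as
#' `inst/extdata/components_synthetic.fasta`.
#'
#' @return an `oligo_components` object.
#' @export
default_components <- function() {
  oligo_components(
    bsmbi_adapter_5 = "CAGATGACTCGTCTCGCACC",
    trcRNA = paste0("GTTTTAGAGCTAGAAATAGCAAGTTAAAATAAGGCTAGTCCGTTATCAACTT",
                    "GAAAAAGTGGCACCGAGTCGGTGC"),
    tRNA = paste0("AACAAAGCACCAG",
                  "TGGTCTAGTGGTAGAATAGTACCCTGCCACGGTACAGACCCGGGTTCGATTCCCGGCC"),
    bsmbi_adapter_3 = "GTTTGGAGACGAAAGGGCCC",
    primers = c("BsmBI-F"    = "CAGATGACTCGTCTCGCACC",
                "trc-tRNA-R" = "CTGGTGCTTTGTTGCACCGA",
                "trc-tRNA-F" = "CCGAGTCGGTGCAACAAAGC",
                "BsmBI-R"    = "GGGCCCTTTCGTCTCCAAAC")
  )
}

#' Read a component set from FASTA
#'
#' Records named `bsmbi_adapter_5`, `trcRNA`, `tRNA`, `bsmbi_adapter_3` define
#' the cassette; records named `primer_<name>` define the amplification
#' primers.
#'
#' @param path FASTA file.
#' @return an `oligo_components` object.
#' @export
read_components_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  seqs <- stats::setNames(as.character(ss), names(ss))
  pr <- seqs[startsWith(names(seqs), "primer_")]
  names(pr) <- sub("^primer_", "", names(pr))
  oligo_components(seqs[["bsmbi_adapter_5"]], seqs[["trcRNA"]], seqs[["tRNA"]],
                   seqs[["bsmbi_adapter_3"]], primers = pr)
}

#' Write a component set to FASTA
#'
#' @param components an `oligo_components` object.
#' @param path output FASTA file.
#' @return `path`, invisibly.
#' @export
write_components_fasta <- function(components, path) {
  seqs <- c(bsmbi_adapter_5 = components$bsmbi_adapter_5,
            trcRNA = components$trcRNA,
            tRNA = components$tRNA,
            bsmbi_adapter_3 = components$bsmbi_adapter_3,
            stats::setNames(unname(components$primers),
                            paste0("primer_", names(components$primers))))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

## the shared scaffold+tRNA block, split rule and junction
spacer_block <- function(components) paste0(components$trcRNA, components$tRNA)

#' Full cassette sequence for a guide pair
#'
#' Direct concatenation `adapter5 + gRNA1 + trcRNA + tRNA + gRNA2 + adapter3`;
#' the reference against which overlap assembly is checked.
#'
#' @param protospacer1,protospacer2 20-nt protospacers (vectorised).
#' @param components an `oligo_components` object.
#' @return character vector of cassette sequences.
#' @export
cassette_sequence <- function(protospacer1, protospacer2, components) {
  paste0(components$bsmbi_adapter_5, protospacer1, components$trcRNA,
         components$tRNA, protospacer2, components$bsmbi_adapter_3)
}

#' Design the synthesis half-oligo for one guide
#'
#' Slot-1 guides yield pool-A oligos (`BsmBI-gRNA1-trcRNA-tRNA...`), slot-2
#' guides pool-B oligos (`...trcRNA-tRNA-gRNA2-BsmBI`); both are 129 nt for a
#' 20-nt protospacer and share a 31-nt junction inside the trcRNA/tRNA block.
#'
#' @param protospacer 20-nt protospacer (vectorised).
#' @param slot 1 or 2.
#' @param components an `oligo_components` object.
#' @return character vector of half-oligo sequences.
#' @export
design_half_oligo <- function(protospacer, slot, components) {
  if (length(protospacer) == 0L) stop("no protospacer given", call. = FALSE)
  if (any(!nzchar(protospacer))) stop("empty protospacer", call. = FALSE)
  assert_dna(protospacer, "protospacer")
  if (!all(slot %in% c(1L, 2L))) stop("slot must be 1 or 2", call. = FALSE)
  glen <- unique(nchar(protospacer))
  if (length(glen) != 1L) {
    stop("protospacers must share one length", call. = FALSE)
  }
  block <- spacer_block(components)
  n <- nchar(block)
  if (all(slot == 1L)) {
    k <- TARGET_HALF_OLIGO_LEN - nchar(components$bsmbi_adapter_5) - glen
    if (k < 1L || k > n) {
      achieved <- nchar(components$bsmbi_adapter_5) + glen + min(max(k, 0L), n)
      stop(sprintf("component lengths cannot yield a %d-nt pool-A oligo (achieved %d)",
                   TARGET_HALF_OLIGO_LEN, achieved), call. = FALSE)
    }
    paste0(components$bsmbi_adapter_5, protospacer, substr(block, 1L, k))
  } else if (all(slot == 2L)) {
    m <- TARGET_HALF_OLIGO_LEN - glen - nchar(components$bsmbi_adapter_3)
    if (m < 1L || m > n) {
      achieved <- glen + nchar(components$bsmbi_adapter_3) + min(max(m, 0L), n)
      stop(sprintf("component lengths cannot yield a %d-nt pool-B oligo (achieved %d)",
                   TARGET_HALF_OLIGO_LEN, achieved), call. = FALSE)
    }
    paste0(substr(block, n - m + 1L, n), protospacer, components$bsmbi_adapter_3)
  } else {
    vapply(seq_along(protospacer), function(i) {
      design_half_oligo(protospacer[i], slot[i], components)
    }, character(1))
  }
}

#' Half-oligos for a whole guide manifest
#'
#' @param manifest guide manifest data frame (`id`, `target`, `protospacer`,
#'   `slot`).
#' @param components an `oligo_components` object.
#' @return named character vector of half-oligos (names = guide ids).
#' @export
design_half_oligos <- function(manifest, components) {
  validate_guide_manifest(manifest)
  stats::setNames(
    design_half_oligo(manifest$protospacer, manifest$slot, components),
    manifest$id
  )
}

#' Overlap-assemble two half-oligos into the full cassette
#'
#' Models the overlap PCR: the largest exact suffix of `oligoA` that is a
#' prefix of `oligoB` (at least `min_overlap` nt) is merged once. Two 129-nt
#' half-oligos sharing the 31-nt trc/tRNA junction give a 227-nt product.
#'
#' @param oligoA pool-A half-oligo (ends in the junction).
#' @param oligoB pool-B half-oligo (starts with the junction).
#' @param min_overlap smallest junction accepted (nt).
#' @return the assembled cassette sequence.
#' @export
assemble_full_cassette <- function(oligoA, oligoB, min_overlap = 15L) {
  assert_dna(c(oligoA, oligoB), "half-oligo")
  lmax <- min(nchar(oligoA), nchar(oligoB))
  overlap <- 0L
  for (l in seq(lmax, min_overlap)) {
    if (substr(oligoA, nchar(oligoA) - l + 1L, nchar(oligoA)) ==
        substr(oligoB, 1L, l)) {
      overlap <- l
      break
    }
  }
  if (overlap == 0L) {
    stop(sprintf("no exact overlap of >= %d nt between half-oligos (failed assembly)",
                 min_overlap), call. = FALSE)
  }
  product <- paste0(oligoA, substr(oligoB, overlap + 1L, nchar(oligoB)))
  junction <- substr(oligoB, 1L, overlap)
  hits <- gregexpr(junction, product, fixed = TRUE)[[1L]]
  if (length(hits[hits > 0L]) != 1L) {
    stop("assembly junction occurs more than once in the product", call. = FALSE)
  }
  product
}

#' Locate BsmBI recognition sites
#'
#' Finds CGTCTC / GAGACG occurrences (both strands) in a sequence.
#'
#' @param x DNA string.
#' @return integer vector of 1-based start positions (both orientations).
#' @export
find_bsmbi_sites <- function(x) {
  pos <- function(pat) {
    p <- gregexpr(pat, x, fixed = TRUE)[[1L]]
    p[p > 0L]
  }
  sort(unique(c(pos(BSMBI_SITE), pos(revcomp(BSMBI_SITE)))))
}

#' Flag cassettes carrying internal BsmBI sites
#'
#' The two adapter sites are required for Golden-Gate cloning; any additional
#' site inside the guide/scaffold region would cleave the construct during
#' cloning, so such cassettes are flagged.
#'
#' @param cassettes character vector of cassette sequences.
#' @param components the `oligo_components` used to build them.
#' @return logical vector: TRUE where an internal (non-adapter) site exists.
#' @export
flag_internal_bsmbi <- function(cassettes, components) {
  a5 <- nchar(components$bsmbi_adapter_5)
  vapply(cassettes, function(s) {
    sites <- find_bsmbi_sites(s)
    interior_start <- a5 + 1L
    interior_end <- nchar(s) - nchar(components$bsmbi_adapter_3)
    any(sites + nchar(BSMBI_SITE) - 1L >= interior_start & sites <= interior_end)
  }, logical(1), USE.NAMES = FALSE)
}

## read-orientation scaffold context flanking each guide, used by the
## deconvolution to trim reads: mate 1 runs into the trcRNA, mate 2 (being the
## reverse complement of the cassette) runs into revcomp(tRNA)
mate_scaffolds <- function(components) {
  list(mate1 = components$trcRNA, mate2 = revcomp(components$tRNA))
}
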