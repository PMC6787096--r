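## Pooled differential-growth screen simulator -------------------------------
##
## Emulates the screen layout: a small slot-1 pool (anchor guides + one
## control) crossed against a genome-style slot-2 pool (3 guides/gene plus
## scrambled controls), read out at T0 and after 14 days of exponential
## growth (modelled as a configurable number of doublings) in two replicates,
## with a known truth table of single-gene and interaction effects.

#' Simulation configuration
#'
#' Study conditions for a synthetic anchored dual-guide screen. Fitness
#' effects are per-doubling log2 growth deficits; a construct's per-doubling
#' growth factor is `2^(e1*s_g1 + e2*s_g2 + [anchor pair] * i_g2)` with `e`
#' the guide efficiencies.
#'
#' @param n_genes number of slot-2 genes.
#' @param guides_per_gene guides per gene in slot 2 (default 3, as in an
#'   optimized genome-wide library).
#' @param n_controls_pos2 scrambled controls in slot 2.
#' @param anchor_guides anchor guides in slot 1 (default 3; one scrambled
#'   control is always added to slot 1).
#' @param anchor anchor gene symbol (default `"TAZ"`).
#' @param doublings population doublings between T0 and T14 (default 10).
#' @param depth sequencing reads per sample; `NULL` means 500 x library size.
#' @param replicates biological replicates per timepoint (default 2).
#' @param dispersion negative-binomial overdispersion of sequencing counts
#'   (default 0.01, which reproduces the ~0.97 replicate log-count
#'   correlations typical of well-powered pooled screens).
#' @param plasmid_sigma log-normal sd (natural log) of initial construct
#'   abundances; the default 0.8 gives a 90:10 representation skew of ~8,
#'   typical of one-step cloned genome-scale libraries.
#' @param effect_sd sd of single-gene per-doubling fitness effects.
#' @param interaction_set data frame with columns `gene` and `effect`
#'   (per-doubling log2 interaction with the anchor); an optional
#'   `single_effect` column overrides the gene's own fitness effect.
#' @param guide_efficiency_range range of per-guide efficiencies in `[0,1]`.
#' @param multinomial if TRUE, draw counts multinomially (exact depth
#'   conservation) instead of negative-binomially.
#' @param seed RNG seed; the same config is bit-reproducible.
#' @return a `screen_config` list.
#' @export
screen_config <- function(n_genes = 200L, guides_per_gene = 3L,
                          n_controls_pos2 = 30L, anchor_guides = 3L,
                          anchor = "TAZ", doublings = 10, depth = NULL,
                          replicates = 2L, dispersion = 0.01,
                          plasmid_sigma = 0.8, effect_sd = 0.05,
                          interaction_set = NULL,
                          guide_efficiency_range = c(0.7, 1),
                          multinomial = FALSE, seed = 1L) {
  stopifnot(n_genes >= 0, guides_per_gene >= 1, n_controls_pos2 >= 0,
            anchor_guides >= 1, replicates >= 1, doublings >= 0,
            dispersion >= 0, plasmid_sigma >= 0, effect_sd >= 0)
  if (!is.null(depth) && depth <= 0) stop("depth must be > 0", call. = FALSE)
  if (any(guide_efficiency_range < 0) || any(guide_efficiency_range > 1)) {
    stop("guide efficiencies must lie in [0,1]", call. = FALSE)
  }
  if (is.null(interaction_set)) {
    interaction_set <- data.frame(gene = character(0), effect = numeric(0))
  }
  structure(list(n_genes = as.integer(n_genes),
                 guides_per_gene = as.integer(guides_per_gene),
                 n_controls_pos2 = as.integer(n_controls_pos2),
                 anchor_guides = as.integer(anchor_guides), anchor = anchor,
                 doublings = doublings, depth = depth,
                 replicates = as.integer(replicates), dispersion = dispersion,
                 plasmid_sigma = plasmid_sigma, effect_sd = effect_sd,
                 interaction_set = interaction_set,
                 guide_efficiency_range = guide_efficiency_range,
                 multinomial = multinomial, seed = as.integer(seed)),
            class = "screen_config")
}

#' Simulate the guide manifests and construct library for a config
#'
#' Slot 1: `anchor_guides` guides for the anchor gene plus one scrambled
#' control. Slot 2: `guides_per_gene` guides for each of `n_genes` genes plus
#' `n_controls_pos2` scrambled controls. Protospacers are random but unique
#' in their 19-nt deconvolution keys.
#'
#' @param config a `screen_config`.
#' @param components optional `oligo_components` (adds cassette sequences).
#' @return list with `pos1`, `pos2` manifests and `library` (the cross
#'   product).
#' @export
simulate_library <- function(config, components = NULL) {
  set.seed(config$seed + 1L)
  genes <- sprintf("GENE%04d", seq_len(config$n_genes))
  n2 <- config$n_genes * config$guides_per_gene + config$n_controls_pos2
  n1 <- config$anchor_guides + 1L
  ## draw until slot-wise 19-mer keys are unique
  draw_unique <- function(n, key_fun) {
    seqs <- random_dna(n, 20L)
    repeat {
      dup <- duplicated(key_fun(seqs))
      if (!any(dup)) return(seqs)
      seqs[dup] <- random_dna(sum(dup), 20L)
    }
  }
  p1 <- draw_unique(n1, function(s) substr(s, 1L, 19L))
  p2 <- draw_unique(n2, function(s) substr(s, 2L, 20L))
  pos1 <- guide_manifest(
    id = c(sprintf("g%s_%d", config$anchor, seq_len(config$anchor_guides)),
           "gCtrl_1"),
    target = c(rep(config$anchor, config$anchor_guides), CONTROL_TOKEN),
    protospacer = p1, slot = 1L)
  pos2 <- guide_manifest(
    id = c(sprintf("g%s_%d", rep(genes, each = config$guides_per_gene),
                   rep(seq_len(config$guides_per_gene), config$n_genes)),
           sprintf("Ctrl2_%04d", seq_len(config$n_controls_pos2))),
    target = c(rep(genes, each = config$guides_per_gene),
               rep(CONTROL_TOKEN, config$n_controls_pos2)),
    protospacer = p2, slot = 2L)
  list(pos1 = pos1, pos2 = pos2,
       library = build_cross_library(pos1, pos2, components))
}

#' Simulate a pooled differential-growth screen
#'
#' Plasmid abundances are log-normal; each construct grows for
#' `config$doublings` doublings with per-doubling factor
#' `2^(e1*s_g1 + e2*s_g2 + [anchor pair] * i_g2)`; sequencing counts are
#' drawn negative-binomially (or multinomially) around the expected
#' proportions at the configured depth for samples
#' `plasmid, T0_rep*, T14_rep*`.
#'
#' @param library construct library data frame ([build_cross_library()]).
#' @param config a `screen_config`.
#' @return list with `counts` (integer matrix constructs x samples),
#'   `sample_info` (sample, timepoint, replicate) and `truth` (gene effects,
#'   guide efficiencies, interaction table, per-construct fitness).
#' @export
simulate_screen <- function(library, config) {
  if (nrow(library) == 0L) stop("empty library", call. = FALSE)
  depth <- config$depth %||% (500 * nrow(library))
  if (depth <= 0) stop("depth must be > 0", call. = FALSE)
  genes <- setdiff(unique(c(library$target1, library$target2)), CONTROL_TOKEN)
  ia <- config$interaction_set
  if (nrow(ia) && !all(ia$gene %in% genes)) {
    stop("interaction gene(s) absent from library: ",
         paste(setdiff(ia$gene, genes), collapse = ", "), call. = FALSE)
  }
  set.seed(config$seed)

  s <- stats::setNames(stats::rnorm(length(genes), 0, config$effect_sd), genes)
  i_g <- stats::setNames(rep(0, length(genes)), genes)
  if (nrow(ia)) {
    i_g[ia$gene] <- ia$effect
    if ("single_effect" %in% names(ia)) s[ia$gene] <- ia$single_effect
  }
  guide_ids <- unique(c(library$guide1_id, library$guide2_id))
  eff <- stats::setNames(stats::runif(length(guide_ids),
                                      config$guide_efficiency_range[1],
                                      config$guide_efficiency_range[2]),
                         guide_ids)
  s0 <- c(s, stats::setNames(0, CONTROL_TOKEN))
  is_anchor_pair <- library$target1 == config$anchor &
    library$target2 != CONTROL_TOKEN
  fit <- eff[library$guide1_id] * s0[library$target1] +
    eff[library$guide2_id] * s0[library$target2] +
    ifelse(is_anchor_pair, i_g[library$target2], 0)
  w <- 2^fit

  n <- nrow(library)
  p_plasmid <- stats::rlnorm(n, 0, config$plasmid_sigma)
  p_plasmid <- p_plasmid / sum(p_plasmid)
  p_t14 <- p_plasmid * w^config$doublings
  p_t14 <- p_t14 / sum(p_t14)

  draw <- function(p) {
    if (config$multinomial) {
      as.integer(stats::rmultinom(1L, size = depth, prob = p))
    } else if (config$dispersion > 0) {
      as.integer(stats::rnbinom(n, mu = depth * p,
                                size = 1 / config$dispersion))
    } else {
      as.integer(stats::rpois(n, lambda = depth * p))
    }
  }
  reps <- seq_len(config$replicates)
  samples <- c("plasmid", paste0("T0_rep", reps), paste0("T14_rep", reps))
  counts <- cbind(draw(p_plasmid),
                  do.call(cbind, lapply(reps, function(r) draw(p_plasmid))),
                  do.call(cbind, lapply(reps, function(r) draw(p_t14))))
  dimnames(counts) <- list(library$construct_id, samples)
  sample_info <- data.frame(
    sample = samples,
    timepoint = c("plasmid", rep("T0", length(reps)), rep("T14", length(reps))),
    replicate = c(NA_integer_, reps, reps), stringsAsFactors = FALSE)
  truth <- list(
    gene_effects = data.frame(gene = genes, single_effect = unname(s[genes]),
                              interaction_effect = unname(i_g[genes])),
    guide_efficiency = data.frame(guide_id = guide_ids, efficiency = unname(eff)),
    construct_fitness = data.frame(construct_id = library$construct_id,
                                   log2_fitness_per_doubling = unname(fit),
                                   anchor_pair = is_anchor_pair),
    depth = depth)
  list(counts = counts, sample_info = sample_info, truth = truth)
}

## substitute sequencing errors into reads at a per-base rate
inject_errors <- function(reads, error_rate) {
  if (error_rate <= 0 || length(reads) == 0L) return(reads)
  width <- nchar(reads)
  nerr <- stats::rbinom(length(reads), width, error_rate)
  hit <- which(nerr > 0L)
  bases <- c("A", "C", "G", "T")
  for (i in hit) {
    ch <- strsplit(reads[i], "", fixed = TRUE)[[1L]]
    pos <- sample.int(width[i], nerr[i])
    for (p in pos) ch[p] <- sample(setdiff(bases, ch[p]), 1L)
    reads[i] <- paste0(ch, collapse = "")
  }
  reads
}

write_fastq_gz <- function(seqs, ids, path) {
  con <- gzfile(path, "wb")
  on.exit(close(con))
  if (length(seqs) == 0L) {
    writeLines(character(0), con)
    return(invisible(path))
  }
  rec <- paste0("@", ids, "\n", seqs, "\n+\n",
                strrep("I", nchar(seqs)))
  writeLines(rec, con)
  invisible(path)
}

#' Emit paired FASTQ files for a simulated count matrix
#'
#' For every construct, exactly its count of read pairs is written per
#' sample: the forward read starts at gRNA1 and runs into the scaffold in
#' cassette sense; the reverse read is the reverse complement of the window
#' ending at the 3' end of gRNA2 (so it starts with revcomp(gRNA2) and runs
#' into revcomp(tRNA)). Substitution errors are injected per base.
#'
#' @param counts integer matrix constructs x samples (rownames =
#'   construct ids).
#' @param library construct library data frame.
#' @param components `oligo_components` defining the cassette.
#' @param dir output directory.
#' @param read_len read length in nt; must cover the 20-nt guide.
#' @param error_rate per-base substitution error probability.
#' @param seed RNG seed.
#' @return sample sheet data frame (`sample`, `fastq1`, `fastq2`).
#' @export
emit_fastq <- function(counts, library, components, dir, read_len = 40L,
                       error_rate = 0, seed = 1L) {
  if (read_len < 21L) {
    stop("read_len too short to cover the 20-nt guide plus scaffold anchor",
         call. = FALSE)
  }
  missing_c <- setdiff(rownames(counts), library$construct_id)
  if (length(missing_c)) {
    stop("constructs absent from library: ",
         paste(utils::head(missing_c, 3L), collapse = ", "), call. = FALSE)
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  lib <- library[match(rownames(counts), library$construct_id), ]
  cass <- cassette_sequence(lib$protospacer1, lib$protospacer2, components)
  a5 <- nchar(components$bsmbi_adapter_5)
  g2_end <- nchar(cass) - nchar(components$bsmbi_adapter_3)
  if (a5 + read_len > nchar(cass)[1L]) {
    stop("read_len exceeds cassette span", call. = FALSE)
  }
  fwd <- substr(cass, a5 + 1L, a5 + read_len)
  rev <- revcomp(substr(cass, g2_end - read_len + 1L, g2_end))
  sheet <- data.frame(sample = colnames(counts),
                      fastq1 = file.path(dir, paste0(colnames(counts), "_R1.fastq.gz")),
                      fastq2 = file.path(dir, paste0(colnames(counts), "_R2.fastq.gz")),
                      stringsAsFactors = FALSE)
  for (j in seq_len(ncol(counts))) {
    k <- counts[, j]
    r1 <- rep(fwd, k)
    r2 <- rep(rev, k)
    if (length(r1)) {
      ord <- sample.int(length(r1))
      r1 <- inject_errors(r1[ord], error_rate)
      r2 <- inject_errors(r2[ord], error_rate)
    }
    ids <- if (length(r1)) {
      paste0(colnames(counts)[j], ":", seq_along(r1))
    } else character(0)
    write_fastq_gz(r1, ids, sheet$fastq1[j])
    write_fastq_gz(r2, ids, sheet$fastq2[j])
  }
  sheet
}

#' Simulate amplicon reads around a Cas9 cut site
#'
#' A fraction of reads carries one edit centred at the cut site (deletion,
#' insertion or substitution per the spectrum); the rest equal the
#' reference window.
#'
#' @param reference amplicon reference DNA string (~100 nt window).
#' @param cut_site 0-based cut position within the reference.
#' @param edit_fraction probability a read is edited.
#' @param edit_spectrum list with `p_del`, `p_ins`, `p_sub` (summing to 1)
#'   and `del_lengths`, `ins_lengths` (integer vectors sampled uniformly).
#' @param n_reads number of reads.
#' @param seed RNG seed.
#' @return list with `reads` (character), `truth` (per-read class/length)
#'   and `edited_fraction` (realised).
#' @export
simulate_amplicon_reads <- function(reference, cut_site, edit_fraction,
                                    edit_spectrum = list(
                                      p_del = 0.6, p_ins = 0.25, p_sub = 0.15,
                                      del_lengths = 1:6, ins_lengths = 1:3),
                                    n_reads = 1000L, seed = 1L) {
  assert_dna(reference, "reference")
  if (edit_fraction < 0 || edit_fraction > 1) {
    stop("edit_fraction must lie in [0,1]", call. = FALSE)
  }
  n_ref <- nchar(reference)
  if (cut_site < 0 || cut_site >= n_ref) {
    stop("cut_site outside reference", call. = FALSE)
  }
  if (max(edit_spectrum$del_lengths) >= n_ref) {
    stop("deletion length exceeds reference span", call. = FALSE)
  }
  set.seed(seed)
  if (n_reads == 0L) {
    return(list(reads = character(0),
                truth = data.frame(read = character(0), class = character(0),
                                   length = integer(0)),
                edited_fraction = NA_real_))
  }
  edited <- stats::runif(n_reads) < edit_fraction
  classes <- rep("WT", n_reads)
  lens <- integer(n_reads)
  reads <- rep(reference, n_reads)
  bases <- c("A", "C", "G", "T")
  types <- c("DELETION", "INSERTION", "SUBSTITUTION")
  pr <- c(edit_spectrum$p_del, edit_spectrum$p_ins, edit_spectrum$p_sub)
  cut1 <- cut_site + 1L  # 1-based base right of the cut
  for (i in which(edited)) {
    ty <- sample(types, 1L, prob = pr)
    classes[i] <- ty
    if (ty == "DELETION") {
      L <- sample(edit_spectrum$del_lengths, 1L)
      start <- cut1 - sample.int(L, 1L) + 1L
      start <- max(1L, min(start, n_ref - L + 1L))
      reads[i] <- paste0(substr(reference, 1L, start - 1L),
                         substr(reference, start + L, n_ref))
      lens[i] <- L
    } else if (ty == "INSERTION") {
      L <- sample(edit_spectrum$ins_lengths, 1L)
      ins <- paste0(sample(bases, L, replace = TRUE), collapse = "")
      reads[i] <- paste0(substr(reference, 1L, cut1 - 1L), ins,
                         substr(reference, cut1, n_ref))
      lens[i] <- L
    } else {
      old <- substr(reference, cut1, cut1)
      new <- sample(setdiff(bases, old), 1L)
      reads[i] <- paste0(substr(reference, 1L, cut1 - 1L), new,
                         substr(reference, cut1 + 1L, n_ref))
      lens[i] <- 1L
    }
  }
  list(reads = reads,
       truth = data.frame(read = paste0("amp", seq_len(n_reads)),
                          class = classes, length = lens,
                          stringsAsFactors = FALSE),
       edited_fraction = mean(edited))
}

#' Simulate a drug-combination inhibition matrix
#'
#' Single-agent inhibitions follow Hill curves
#' `i(d) = d^h / (d^h + ec50^h)`; combined cells are the Bliss expectation
#' plus a planted additive excess plus Gaussian noise, clipped to `[0,1]`.
#' Dose 0 rows/columns reproduce the other agent's single-agent curve.
#'
#' @param doses_A,doses_B dose vectors; a leading 0 (vehicle) is added when
#'   absent.
#' @param hill_A,hill_B lists with `ec50` and `h`.
#' @param excess additive Bliss excess planted in every combination cell.
#' @param noise_sd sd of Gaussian noise (must be >= 0).
#' @param seed RNG seed.
#' @return inhibition matrix with dose dimnames; `[1,1]` (vehicle) is 0.
#' @export
simulate_viability_matrix <- function(doses_A, doses_B,
                                      hill_A = list(ec50 = 1, h = 1.5),
                                      hill_B = list(ec50 = 1, h = 1.5),
                                      excess = 0, noise_sd = 0, seed = 1L) {
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (any(doses_A < 0) || any(doses_B < 0)) {
    stop("doses must be non-negative", call. = FALSE)
  }
  if (doses_A[1L] != 0) doses_A <- c(0, doses_A)
  if (doses_B[1L] != 0) doses_B <- c(0, doses_B)
  hill <- function(d, p) ifelse(d == 0, 0, d^p$h / (d^p$h + p$ec50^p$h))
  iA <- hill(doses_A, hill_A)
  iB <- hill(doses_B, hill_B)
  expected <- outer(iA, iB, function(a, b) a + b - a * b)
  obs <- expected
  interior <- outer(doses_A > 0, doses_B > 0, `&`)
  obs[interior] <- obs[interior] + excess
  if (noise_sd > 0) {
    set.seed(seed)
    noise <- matrix(stats::rnorm(length(obs), 0, noise_sd), nrow = nrow(obs))
    noise[1L, 1L] <- 0
    obs <- obs + noise
  }
  obs <- pmin(pmax(obs, 0), 1)
  dimnames(obs) <- list(doses_A, doses_B)
  obs
}
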