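---
title: "Anchored dual-guide CRISPR interaction screens: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Anchored dual-guide CRISPR interaction screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tcgi)
```

## The experiment this package models

A tRNA-spaced dual-guide CRISPR screen expresses two sgRNAs from one U6
transcript, separated by a tRNA whose excision by endogenous RNase P/Z
releases both guides. Position 1 carries either a guide against a fixed
*anchor* gene (TAZ/WWTR1 in the motivating screen) or a scrambled
non-targeting control; position 2 carries a genome-scale pool (3 guides per
gene) plus scrambled controls. Crossing the two pools yields every
anchor--gene double knockout alongside the matched single knockouts and
control--control pairs in one library. Cells are transduced at low MOI,
selected, and sampled at T0 and after 14 days of exponential growth; the
depletion of each construct between the two timepoints (log2 fold change,
"logFC") is its fitness phenotype. A gene is *synergistic* with the anchor
when the double-knockout phenotype exceeds what the single knockouts
explain.

The package implements the complete computational side of that experiment:
library design (`design_half_oligo`, `build_cross_library`,
`generate_scrambled_controls`), screen simulation with a known truth table
(`screen_config`, `simulate_screen`, `emit_fastq`), read deconvolution
(`count_screen`), the interaction-scoring chain (`score_screen`), amplicon
indel quantification (`align_to_amplicon`, `cleavage_rate`) and the small
validation statistics (`bliss_excess`, `percent_transduction`,
`relative_foldchange`, `validation_accuracy`).

## Oligo architecture

Each library member is synthesised as two 129-nt half-oligos sharing a
31-nt junction inside the scaffold/tRNA block and merged by overlap PCR into
a 227-nt cassette:

```
adapter5(20) - gRNA1(20) - trcRNA(76) - tRNA(71) - gRNA2(20) - adapter3(20)
```

The printed amplification primers fix the adapter sequences and the 13 nt of
the tRNA adjacent to the scaffold; the trcRNA default is the canonical
76-nt S. pyogenes sgRNA scaffold; the remainder of the tRNA body is
synthetic filler chosen to satisfy the length constraints. The shipped
component file is therefore named `components_synthetic.fasta` and should be
replaced by the real component sequences for actual synthesis. Components
are configuration, not constants: any FASTA with the same record names can
be supplied. Designed cassettes are additionally scanned for internal BsmBI
sites (`flag_internal_bsmbi`), because a recognition site outside the two
cloning adapters would destroy the construct during Golden-Gate assembly;
junction-spanning sites created by an unlucky protospacer do occur and are
flagged.

## The simulator: what it emulates and what it does not

`simulate_screen()` draws initial construct abundances log-normally
(`plasmid_sigma`, default 0.8 on the natural log scale, a 90:10
representation skew of about 8, typical of one-step cloned genome-scale
libraries), grows each construct for `doublings` doublings (default 10 for
the 14-day window; the paper-style experiment does not state a doubling
time) with per-doubling growth factor

$$w = 2^{\,e_1 s_{g1} + e_2 s_{g2} + \mathbf{1}[\text{anchor pair}]\, i_{g2}}$$

where $s_g$ are per-doubling single-gene log2 fitness effects, $i_g$
per-doubling interaction effects with the anchor, and $e \in [0.7, 1]$
per-guide efficiencies (an optimized guide library). Sequencing counts are
drawn negative-binomially around the expected proportions at the configured
depth, with overdispersion 0.01 by default; this value was chosen to
reproduce the replicate concordance reported for well-powered screens of
this design (Pearson correlation of log10 counts between biological
replicates near 0.97, Spearman correlation near 0.98 between plasmid and
T0) -- a naive choice of 0.1 gives replicate correlations near 0.7, nothing
like real screen data. A `multinomial = TRUE` switch conserves depth
exactly and is used by the round-trip identity tests.

Fitness is additive in log-growth with multiplicative guide efficiency --
the simplest model consistent with the additive single-effect adjustment
used downstream; it is a stand-in, not a biological claim. The simulator
does not model lentiviral infection statistics, template-switching
recombination between the two half-cassettes, or PCR jackpots; the wet-lab
artifact of truncated single-guide products is removed by gel purification
in the protocol and is likewise not simulated, so every read pair
represents a full cassette.

`emit_fastq()` writes one read pair per counted construct: the forward read
starts at gRNA1 and runs into the scaffold; the reverse read is the reverse
complement of the window ending at gRNA2, so it begins with revcomp(gRNA2)
and runs into revcomp(tRNA). Substitution errors are injected per base.

## Deconvolution rules

Reads are trimmed at the first exact occurrence of a 12-nt scaffold anchor
(the trcRNA for mate 1, revcomp(tRNA) for mate 2), truncated to 19 nt from
the guide-proximal end, and mate-2 keys reverse-complemented into cassette
sense. The 19-nt truncation is implemented as specified by the protocol
even though its motivation is not stated; the practical consequence is that
slot-1 guides are identified by their first 19 nt and slot-2 guides by
their last 19 nt, and manifests must be unique in those keys (collisions
are an error naming the colliding key). Matching is exact hash lookup by
default with an optional one-mismatch expansion (`tolerance = 1`);
"alignment" of fixed-length tags to a known dictionary does not need a
full aligner. Reads without a usable key are rejected; pairs whose two keys
match guides that never co-occur in a library construct are counted
*discordant* rather than assigned, and `mapped + unmapped + discordant`
always equals the number of input pairs. Which mate carries gRNA1, and a
positional fallback for scaffold-free trimming, are configurable because
the read layout is a property of the sequencing design, not of the method.

## The scoring chain

`score_screen()` applies, in order:

1. **Background correction** (`background_correct`): per sample, the median
   count of the control--control constructs is subtracted from every
   construct, results are floored at 0, and the control--control rows are
   dropped.
2. **Abundance filter** (`cpm_filter`): keep constructs with at least 5
   counts per million in at least 2 samples. Note that at genome scale
   (231,728 constructs) the mean construct abundance is 4.3 CPM, so this
   threshold retains only the upper tail of the library; at desk scale the
   same absolute threshold is much more permissive, and callers who want
   scale-equivalent stringency should raise `min_cpm` toward
   `1e6 / n_constructs`.
3. **TMM normalization** (`tmm_factors`): the published trimmed-mean-of-M
   estimator with M-trim 0.30 and A-trim 0.05, computed via edgeR; an
   independent direct-formula implementation in the test suite pins the
   factors to 1e-8.
4. **Differential abundance** (`differential_abundance`): classic edgeR
   negative-binomial two-group model, T14 vs T0, with TMM-scaled effective
   library sizes, robust empirical-Bayes tagwise dispersion (robustness
   matters: background-corrected matrices contain rows whose counts were
   floored to zero in some samples, and a non-robust prior lets those rows
   inflate everyone's dispersion and destroy power), exact test p-values
   and Benjamini--Hochberg FDR. Depletion at T14 is negative logFC.
5. **Interaction calls** (`call_interactions`): per gene, three arms are
   aggregated from construct logFC -- single knockout (gCtrl--gTarget), raw
   double (gAnchor--gTarget) and anchor alone (gAnchor--gCtrl). The anchor
   phenotype is subtracted from the raw double phenotype (additive in log
   space, the standard genetic-interaction convention; a `divide` variant
   is exposed because the verbal description of the adjustment admits both
   readings), and the ratio
   $r = P_{\text{single}} / P_{\text{double,adj}}$ is compared with 0.5:
   genes with $r < 0.5$ -- the adjusted double effect more than twice the
   single effect -- are called synergistic.

Three decisions in step 5 deserve explanation.

* **Construct-level FDR gate.** Only constructs with FDR < 0.1 contribute
  to the single and double arm means (the `gate` argument exposes a
  no-gating variant). An arm with *no* significant construct is assigned
  phenotype 0: "no detectable effect" is itself a phenotype, and treating
  it as missing would make genes whose single knockout is truly neutral --
  exactly the most interesting synergy candidates, with $r \to 0$ --
  uncallable.
* **The anchor-alone arm is aggregated without the FDR gate**
  (`gate_anchor = FALSE`). That arm estimates a nuisance offset centred
  near zero; keeping only its significant constructs retains nothing but
  selection-biased extremes and was observed to corrupt the adjustment by
  many log2 units. A nuisance parameter should be estimated from all its
  replicates, not from its outliers.
* **Sign policy and floor.** Ratios of mixed-sign phenotypes are
  meaningless. A gene is only scored when the adjusted double phenotype
  shows real depletion ($P_{\text{double,adj}} < -0.5$ log2, i.e. at least
  ~1.4-fold beyond the anchor's own effect -- arm means smaller than that
  are at the noise scale of this chain) and the single phenotype does not
  show enrichment ($P_{\text{single}} \le 0$). Everything else is reported
  `UNDEFINED` and never called.

## Known limitations of the published chain

The median background correction subtracts a value of the same order as a
typical construct's count (control--control pairs are ordinary library
members), so roughly half of all constructs are floored to zero in every
sample, and constructs whose abundance sits near the control median in one
timepoint but not the other acquire spurious extreme logFC. On simulated
screens with a *realistic spread of single-gene fitness effects*
(`effect_sd = 0.05` per doubling), this amplification converts modest true
fitness depletion into false synergy calls: we measure a per-gene false
call rate around 0.25 in that regime, against ~0.002 on a fitness-neutral
background. Recovery of genuine interactions is robust (recall above 0.9 at
depth 500 reads per construct in both regimes), but callers should treat
the ratio calls on fitness-active genes with caution and consider the
`gate = "none"` aggregation plus a stricter `floor` when the anchor itself
has a strong growth phenotype. This behaviour is a property of the
published procedure, faithfully implemented, not of this implementation.

The planted-interaction acceptance property is therefore evaluated on a
fitness-neutral background with interactors planted at `single_effect = 0`
-- the same construction as the module's own recovery example -- which
isolates the interaction-detection path from the background-correction
artifact.

## Indel quantification and synergy statistics

Amplicon reads are globally aligned to the ~100-nt wild-type window with
affine gap penalties (match +2, mismatch -3, gap open -5, gap extend -1 per
base; all configurable, since the protocol names no aligner), with an
identity floor of 0.6 below which a read is `UNALIGNED`. Indels overlapping
a +/-10-nt window around the cut site are classified with the largest event
winning; substitutions count toward the cleavage rate by default
(`include_substitutions = FALSE` restricts to indels), because the
figure-level categories include point mutations. The cleavage rate is the
edited fraction of aligned reads; unaligned reads are excluded from the
denominator and reported separately. The alignment is cross-checked in the
test suite against an independent Gotoh dynamic-programming oracle on
exhaustive small instances.

Bliss independence expects combined inhibition $i_A + i_B - i_A i_B$ from
the single-agent margins; the synergy score is the mean observed-minus-
expected excess over the combination cells, in percentage points. Small
negative inhibitions (down to -0.1, from viability slightly above the
vehicle control) are clipped to zero before the check by default, since
the protocol does not state its handling. Percent transduction, relative
proliferation fold change and validation accuracy are direct
implementations of their printed formulas.

## Problem sizes and reproducibility

All simulations are bit-reproducible under a fixed seed at every operation.
The analysis scripts and the test suite run at desk scale: 50--200 genes,
3 guides per gene, 2 replicates, depths of 500 reads per construct for
scoring experiments and 2x10^5 reads per sample for round-trip
deconvolution; the acceptance script's recovery experiment uses 5 seeded
200-gene screens with 5 interactors planted at -2 log2 per doubling. Every
number reported in the README and in `results/` is produced by running the
code.
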