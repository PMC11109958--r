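---
title: "Measuring strand-resolved histone deposition around replication origins"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring strand-resolved histone deposition around replication origins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(espanr)
```

## The measurement problem

When a replication fork passes, the parental histone H3–H4 tetramers ahead
of it are recycled onto one of the two nascent strands: the continuously
synthesized leading strand or the discontinuously synthesized lagging
strand. Strand-resolved sequencing of protein-associated nascent DNA
(eSPAN: a chromatin IP for a histone mark, followed by an IP of the
BrdU-labelled nascent single strand) yields reads whose mapping strand
records which nascent strand carried the mark. Around a bidirectional
origin the geometry converts strand into pathway: with Watson defined as
the reference forward strand, a rightward-moving fork synthesizes its
leading strand as Watson, so at nucleosomes *left* of an origin the
lagging nascent strand is Watson and at nucleosomes *right* of it the
lagging strand is Crick.

The core statistic is, at each of the ten positioned nucleosomes flanking
each side of an origin (indices $-10..-1$, $+1..+10$; the origin itself
sits in a nucleosome-free region, so there is no position 0),

$$ b_{ij} = \log_2 \frac{W_{ij} + c}{C_{ij} + c} $$

where $W_{ij}$ and $C_{ij}$ are the Watson- and Crick-mapped fragment
counts of origin $i$ at nucleosome $j$ and $c$ is a pseudocount. A mark
deposited preferentially on the lagging strand with probability $p$ gives
an expected bias of $+\log_2\!\big(p/(1-p)\big)$ at left-side nucleosomes
and the negative of that on the right. Averaging $b_{ij}$ over origins
position-by-position gives the bias profile; sign-flipping the right side
and merging by nucleosome distance ("folding") puts everything on a single
lagging-strand axis.

## The pipeline

The analysis chain is: size-select fragments to the mononucleosome window
(120–170 bp inclusive, from the paired-end insert length), separate
strands, assign each fragment to the unique nucleosome interval that
contains its midpoint (`floor((start+end)/2)`; intervals are half-open, so
ties cannot occur), accumulate the (origin, position, strand) counts
tensor, and form the bias matrix and profile.

```{r espan}
gf <- make_genome(n_origins = 20, n_genes = 10, chrom_length = 2e5)
geno <- genotype_params("dpb3-like", p_lagging = 0.75, depth = 400,
                        background = 0, seed = 42)
frags <- filter_fragments(simulate_espan(gf, geno, "parental"))
counts <- count_by_nucleosome(frags, gf$origin_nucs)
profile <- average_bias_profile(bias_matrix(counts, pseudocount = 1))
head(profile, 3)
mean(fold_leading_lagging(profile)$mean)   # ~ log2(0.75/0.25) = 1.585
```

## The synthetic-data generator

Real eSPAN data require the sequenced libraries and a curated origin and
nucleosome-position map, so the package ships a generator that emulates
the statistical structure the analysis assumes, with known ground truth:

* **Geometry** — origins evenly spaced on one chromosome, each with a
  140 bp nucleosome-free region and ten nucleosomes per side at a 165 bp
  repeat (typical budding-yeast values; both configurable). Genes live on
  a second chromosome with an NFR at the TSS and six downstream
  nucleosomes.
* **Strand model** — a parental-mark fragment is Watson with probability
  `p_lagging` left of the origin and `1 - p_lagging` right of it; the
  new-mark probabilities are the complement, reflecting that new histones
  fill the strand the parental ones avoided. `p_lagging` is a per-genotype
  dial: the shipped presets are illustrative (wild type 0.55 — a slight
  lagging preference; a Dpb3-loss-like preset 0.80; an Mcm2-axis preset
  0.20; the double mutant back to 0.55), not measurements.
* **Fragments** — lengths Normal(148, 8) clipped to 120–170 bp
  (149–170 bp and Normal(157, 8) for MNase), midpoints jittered
  Normal(0, 20 bp) around the dyad, plus a uniform background fraction
  (default 0.05) with fair strand choice. Fragment counts are exact:
  `depth` per origin side plus the implied background count.
* **Phenotypes** — flow events multinomial over RFP+GFP+ / RFP+GFP− /
  other; selective-plate colonies Binomial(cells plated, frequency);
  focus-positive cells Binomial(cells per field, probability).

Every simulation call takes an explicit seed and runs in its own RNG
stream (`withr::with_seed`), so outputs are byte-identical across runs
and no global state leaks.

What the generator deliberately does **not** emulate: origin-to-origin
replication-timing differences and fork asymmetries, mappability and GC
artefacts, BrdU incorporation efficiency, IP specificity, PCR duplicates,
and nucleosome-map errors. Passing recovery tests therefore demonstrates
that the statistics are implemented correctly and are identifiable under
the stated model, not that real libraries are free of these confounders.

## MNase-seq metaprofiles

Nucleosome occupancy is fragment coverage: every base under a 149–170 bp
fragment counts once. For each anchor (TSS or origin) the coverage in a
±500 bp window (configurable; examples below use ±400 bp to keep the
genic windows clear of neighbouring anchors) is standardized to mean 0
and unit variance *per region* — population variance, since the window
is the entire population of positions, tested to 1e-9 — then averaged
position-wise over anchors with equal weight. Minus-strand anchors are
reversed first so positive offsets always point downstream. A
constant-coverage window has no positional information and is excluded
rather than averaged as zeros.

Nucleosomal coverage peaks are flat-topped (the positioning kernel
convolved with the ~150 bp footprint), so a raw argmax wanders on the
plateau by ~±12 bp at realistic depth; `profile_peaks()` applies a 41 bp
running mean before the argmax, which centres the plateau and localizes
dyads to a few bp:

```{r mnase}
fr <- filter_fragments(simulate_mnase(gf, positioning_sd = 20,
                                      depth = 5e4, seed = 7), 149, 170)
track <- coverage_track(fr, gf$chrom_lengths)
mp <- metaprofile(track, data.frame(chrom = gf$tss$chrom,
                                    pos = gf$tss$pos,
                                    strand = gf$tss$strand),
                  half_width = 400)
profile_peaks(mp, expected = 70 + (1:2 - 0.5) * 165)
```

Two size windows coexist by design: 120–170 bp where occupancy is
computed from eSPAN-style libraries, 149–170 bp for MNase-seq profiles;
both are arguments to `filter_fragments()`.

## Phenotype statistics

* `silencing_loss_rate()` — RFP+GFP+ events divided by the cells able to
  lose silencing (RFP+GFP+ plus RFP+GFP−); other events never enter the
  denominator; an empty denominator is flagged missing.
* `hr_frequency()` — per replicate colony, selective-plate count over
  viable cells (viable count × dilution); the strain statistic is the
  median over replicates (even count: mean of the central pair), which is
  robust to the jackpot replicates that plague recombination counts.
  `relative_hr()` is a ratio of medians, not a mean of per-replicate
  ratios — the latter is dominated by whichever replicate of the
  denominator strain is smallest.
* `foci_fraction()` — percent of focus-positive cells per imaging field,
  mean ± SEM over fields (SEM is sample SD/√n throughout).
* `one_way_anova()` — the classical equal-variance F test
  (`stats::oneway.test`), as used for strain comparisons; all-identical
  input is flagged undefined instead of returning 0/0. No
  multiple-comparison correction is applied by default, matching how
  per-strain comparisons are conventionally reported for these assays;
  p-values are returned so callers can apply `p.adjust` if desired.
* `soluble_histone_ratio()` — blot signal over the PGK1 loading control,
  rescaled so the reference strain's mean is 1; invariant to a common
  exposure factor.

## Numerical and design choices

* **Coordinates** are 0-based half-open everywhere (BED-native); SAM
  input is converted at the boundary. Readers report malformed lines by
  line number; all writer/reader pairs round-trip exactly.
* **Pseudocount** defaults to 1 so that all 20 positions stay defined at
  low depth; `pseudocount = 0` gives the literal log-ratio with
  zero-count cells marked missing. The bias is computed as
  `log2(W + c) − log2(C + c)`, a difference of logs, so swapping strand
  labels negates every finite cell bit-exactly.
* **Averaging** uses the arithmetic mean of per-origin log-ratios, which
  at low counts shrinks slightly toward zero relative to
  $\log_2(p/(1-p))$ (Jensen effect, ~0.05 at ~19 fragments per strand
  per cell); recovery checks therefore run at aggregate depths where
  this is inside their tolerance.
* **Alignment strand** comes from the first-in-pair read: these
  libraries are strand-preserving single-strand libraries, so insert
  orientation is meaningful. Duplicate removal is exposed as a flag,
  default off.
* **Heatmap row order** is genomic coordinate order; a minimum-reads
  filter per origin is available but defaults to keeping all origins.
* **Problem sizes** in the shipped checks — 134 origins with ~1e5
  fragments for bias recovery, 1e5 MNase fragments, the assay's own
  sizes (10 colonies × 50 000 events; 6 replicates; 3 fields × 500
  cells) for phenotypes — were chosen so that each statistic's sampling
  error is several times smaller than the effect it must resolve.

## Limitations

The bias statistic assumes the provided nucleosome map is correct and
that Watson/Crick is meaningful per reference orientation; origins that
fire rarely or are passively replicated dilute the signal in real data.
BrdU enrichment is not modelled as a separate step: inputs are assumed
already nascent-strand-resolved, which is what the double-IP produces.
The ANOVA assumes approximately equal within-group variance; with the
small replicate counts typical of these assays it has limited power, and
the package reports effect summaries (means, SEMs, medians) alongside
p-values for that reason.
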