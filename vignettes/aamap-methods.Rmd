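---
title: "Scoring per-residue essentiality from tiling CRISPR screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring per-residue essentiality from tiling CRISPR screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aamap)
```

## The experiment this package analyses

A tiling CRISPR screen mutagenises every reachable position of a target
gene: sgRNAs are designed at every NGG and NAG PAM along the coding
sequence, so Cas9 cuts, and the ensuing error-prone repair plants indels
and occasional point mutations, throughout the protein. After a positive
selection (a toxin or drug that kills cells with a functional target),
cDNA of the target is amplified, fragmented to roughly 250 bp, and
sequenced deeply, both before and after selection. Reads carrying
in-frame changes report which amino acids the selection cares about:
in-frame events at critical residues are enriched in survivors, while
frameshifts carry no positional information (they null the protein
wherever they land).

The analysis pipeline turns those fragments into a per-residue
*essential score*. The stages, each its own module surface:

1. **Reference and design** (`load_cds`, `design_sgrnas`): validate the
   CDS, map nucleotide to codon coordinates, and enumerate every 23-nt
   window ending in NGG/NAG on either strand. The cut site follows the
   blunt-cut convention 3 bp 5' of the PAM; minus-strand cuts are
   mirrored into plus-strand coordinates. Coordinates are 0-based
   half-open internally; residues are 1-based everywhere a user sees
   them.
2. **Effect extraction** (`read_alignments`, `call_effects`): parse
   primary alignments, drop reads with mean base quality below 30,
   compare M blocks base-by-base (maximal mismatch runs merge into one
   substitution variant), classify the frame from the net indel length,
   and translate in-frame changes.
3. **Quantification** (`effect_frequencies`, `substitution_frequency`):
   per-effect-type frequencies with full-containment coverage
   denominators.
4. **Scoring** (`fold_changes`, `aggregate_deletion_fc`,
   `aggregate_combo_fc`, `substitution_cutoff`, `essential_scores`,
   `score_cutoff`).
5. **sgRNA readout** (`count_spacers`, `sgrna_log2fc`,
   `replicate_correlation`): the conventional barcode-counting view of
   the same screen, used for QC.
6. **Simulation** (`simulation_config`, `simulate_screen`): a complete
   generative model of the screen, used throughout the test suite.

## Effect translation

A read's variants are applied to the CDS, both proteins are translated,
and the longest common prefix, then the longest common suffix, are
trimmed at the residue level (prefix first — the tie-break that makes
calls canonical when a deletion could be placed at several equivalent
positions). What remains defines the affected reference interval and the
replacement residues, and hence the category:

* `aa_deletion` — residues lost, nothing gained;
* `combo` — net length change with replacement residues (the combined
  effect of an in-frame deletion and a missense change at its junction);
  pure in-frame insertions are folded in here and flagged;
* `substitution` — same length, at least one changed residue;
* `silent`, `wildtype`, `frameshift` — carry no in-frame positional
  signal and are excluded from scoring;
* `nonsense` — an in-frame change whose replacement contains a premature
  stop. These are truncation alleles, phenotypically null. They are
  excluded from scoring like frameshifts: in simulated recessive screens
  the double-null resistant population otherwise leaks truncating
  in-frame deletions into the combo channel as false-positive enrichment
  at non-critical residues.

Reads whose alignment does not fully contain the codon-extended
footprint of their own effect cannot be translated unambiguously; they
are kept in the table but flagged `callable = FALSE` and never counted.

The "base quality below 30" filter is applied to the read mean by
default (configurable to a per-base minimum): the mean matches common
read-filtering semantics and keeps long fragments with isolated
low-quality tails.

## Frequencies, fold changes, and the essential score

For an effect key (one identical amino-acid-level event) the frequency
is `reads_with_event / reads_fully_covering_its_footprint`. Full
containment is required of denominator reads because a partial overlap
cannot establish presence or absence of the whole event. Keys supported
by fewer than 9 reads are removed (5 for the cut-site mutation-variety
profile); residues with zero coverage are reported missing, never zero.

Fold changes divide after-selection by before-selection frequencies; a
key absent after selection is a genuine depletion (fold change 0), while
a key absent before selection has no denominator and is excluded.
Per-residue aggregation gives a single-residue deletion its full weight
`w` (default 1) and discounts a key spanning `len` residues by
`1/len^2`, shared by every residue in its span; combo keys always use
the discount, including length-1 keys. Keys affecting more than 3
residues are dropped — long events smear positional signal and raise the
false-positive rate.

Substitutions cannot be quantified against the before library: the
sequencing/PCR error background is itself dominated by point changes, so
the before-library substitution signal is indistinguishable from error.
They are scored qualitatively instead: with `Freq_sub` the per-residue
substitution frequency after selection, the cutoff is
`mean(log10 Freq_sub) + 3 sd(log10 Freq_sub)` over residues with
positive frequency, and a residue strictly above it receives
`sf_score = 2`, otherwise 0.

The quantitative part z-scores `log10(dfc_aa + cmfc_aa)` over residues
with a positive aggregate and converts `z` to an upper-tail
standard-normal probability; the normalization makes the score invariant
to a global rescaling of fold changes (for example from selection-pool
dilution). The essential score is `-log10(p) + sf_score`; ranks break
ties by residue index. The normalization-and-tail construction is
isolated in one function so an alternative reference distribution can be
swapped in.

The hit cutoff is `mean + k_sd * sd` of the essential scores with
`k_sd = 3` by default, exposed as a parameter (see limitations).

Replicates are scored separately and averaged per residue before
re-ranking (`combine_replicate_scores`); pooling reads before scoring is
the alternative when replicates differ greatly in depth.

## The simulator

`simulate_screen` generates a full screen from a `simulation_config`:

* a random CDS (`protein_length` residues, default 200) and its tiling
  sgRNA library;
* `n_cells` cells (default 20,000), each carrying **one** sgRNA chosen
  uniformly — as in a pooled screen infected at low multiplicity — with
  each of its `ploidy` (default 2) alleles independently edited with
  probability `edit_rate` (default 0.5) at that sgRNA's cut site;
* edit outcomes: with probability `missense_rate` (default 0.1) a 1-nt
  substitution at the cut; otherwise an indel drawn from a
  deletion-skewed spectrum (deletions of 1-12 nt with probability
  proportional to 0.7^len, 90% of the mass, plus 1-2 nt insertions).
  Deletions are centred on the cut site, mimicking bidirectional
  resection; one canonical placement per (cut, length) keeps the read
  support of each variant type at desk-scale depths above the count
  filter, which a uniformly-placed spectrum would dilute roughly
  four-fold;
* allele classes derived by the package's own effect translation:
  frameshift or nonsense alleles are null; in-frame changes touching a
  planted critical residue are function-altering; everything else is
  functional. A cell is resistant (recessive model) when no functional
  allele remains, or (dominant model) when any allele is
  function-altering; for essential genes the all-null genotype dies;
* sequencing: `depth` fragments per condition (default 2e5), lengths
  Normal(250, 25), uniform positions, per-base substitution errors at
  `seq_error_rate` (default 1e-3), written with truth alignments
  (correct POS/CIGAR), so the extraction module is exercised without an
  external aligner. The after library weights cells by
  `enrichment^resistant` (default 50); the mock library is pure wild
  type plus sequencing error.

`edit_rate = 0.5` was chosen so that double-frameshift (all-null)
resistant cells do not dominate the selected pool: at higher edit rates
their enrichment dilutes every frequency in the after library and
compresses the fold changes of the informative in-frame keys.
`n_cells = 20000` gives each recurrent variant type enough carrier
alleles that its before-library read count clears the min-count filter
at the default depth.

What the simulator does **not** model: sequence-dependent repair
spectra, allele-specific expression or nonsense-mediated decay (beyond
the essential-gene removal rule), PCR duplicates and indel-type
sequencing errors, multiple sgRNA integrations, and growth dynamics
beyond a single enrichment multiplier. Passing recovery tests on this
model therefore demonstrates the pipeline's arithmetic and its
behaviour under sampling noise, not robustness to the full error
structure of real libraries.

## Assayability and benchmark design

A residue can only acquire in-frame signal if cut sites fall close
enough that an in-frame deletion can cover its codon, and it can only
receive a full-weight single-residue deletion key if some cut sits at
its codon's second base (a centred 3-nt deletion then excises exactly
that codon). `assayable_residues` reports both conditions. The recovery
benchmarks in the test suite plant critical residues drawn evenly from
the assayable set — a residue the library cannot reach in frame is not
a meaningful recovery target, which mirrors the coverage caveat any
real tiling screen states for its own maps.

## Problem sizes and numerical choices

The test suite and the acceptance script run synthetic screens of 200
residues at 2e5 reads per condition, with 3 positive seeds and a bank
of null (no-selection) seeds; smaller pools are used for unit tests.
Sample standard deviations (n-1) are used in both cutoffs; both cutoffs
use strict inequality, so ties are non-hits. A degenerate spread
(all-equal positive aggregates) yields z = 0 for all, with a warning.
Deterministic behaviour is part of the contract: identical
configuration and seed give byte-identical simulator output and
pipeline tables.

## Known limitations

* **Null false positives at the default cutoff.** The quantitative part
  of the score is `-log10` of an upper-tail probability, an
  exponentially-tailed quantity. With on the order of a hundred scored
  residues, the largest null score is comparable to `mean + 3 sd` of
  the score distribution, so a no-selection screen yields one or two
  residues above the default cutoff in a substantial minority of seeds
  (the test suite measures this directly). Raising `k_sd` to 4 cleans
  the null but also removes the weakest true planted residues — those
  covered only by length-discounted multi-residue keys — from the hit
  list. No value of `k_sd` separates the two regimes on this model at
  these depths: the overlap is a property of within-screen z
  normalization, which maps the top of any screen's distribution, null
  or not, to similar scores. Treat the cutoff as a visual aid, as the
  dashed line it draws, and the rank ordering as the primary output.
* Substitution scoring is qualitative by construction; at desk-scale
  depths the per-residue substitution frequency is dominated by the
  uniform error background, so `sf_score` rarely fires in simulation.
  In real screens with several selection rounds the enrichment at truly
  critical residues is far larger.
* Amplicon stitching (per-amplicon denominators summed across
  overlapping amplicons) is supported at the interface level via the
  alignment offset, but the simulator generates single-amplicon screens
  only.
* Reads carrying both an in-frame indel and a distant isolated
  substitution produce one composite effect via trimming; the distant
  substitution is not separately counted toward `Freq_sub`.
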