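---
title: "Quantifying transcription and RNA decay from pA+/pA- 3'-end sequencing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying transcription and RNA decay from pA+/pA- 3'-end sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ends3p)
library(dplyr)
```

## The measurement

Oligo-dT-primed 3'-end sequencing reads start at an RNA's 3' terminus, so
the 5' end of each aligned read marks one RNA 3' end at single-nucleotide
resolution. Sequencing the same RNA twice — once directly (pA-selected,
detecting only polyadenylated 3' ends) and once after in vitro E-PAP
tailing (detecting polyadenylated *and* non-polyadenylated ends) — lets
the non-polyadenylated (pA-) signal be computed by subtraction. Applied
to total RNA and to RNA metabolically labeled with a short 4-thiouracil
(4tU) pulse, the resulting four tracks separate three biological
quantities:

* **Transcription**: pA- 3' ends inside gene bodies are predominantly
  the positions of elongating polymerases (the nascent RNA's 3' end sits
  in the RNAP active site), so their *density* over the gene body is a
  transcription proxy.
* **RNA level**: pA+ signal around the transcript end site (TES) counts
  mature molecules.
* **Decay**: the ratio of labeled to total RNA after a pulse of length
  $t$ follows first-order kinetics.

The pipeline in this package turns per-sample single-nucleotide 3'-end
tracks into those quantities in a fixed stage order:

1. extract RNA 3' ends from alignments (reverse-protocol orientation),
2. mask genomic internal-priming artifacts (the "A-mask"),
3. count spike-in features and derive median-of-ratios size factors,
4. scale tracks and drop spike-in chromosomes,
5. subtract the mock-IP background from labeled samples,
6. derive pA- = (pA+,-) − (pA+) — *after* background subtraction for
   labeled samples; the order matters because subtraction does not
   commute with the positive-part truncation,
7. quantify gene-body and gene-end regions, splice junctions, metagene
   matrices, and decay rates.

## Model and estimators

For a gene with initiation rate $\mu$ (events/min), first-order decay
rate $k$ (min$^{-1}$) and elongation speed $v$ (nt/min):

* steady-state mature abundance: $\mu/k$;
* labeled mature fraction after a pulse of $t$ minutes:
  $1 - e^{-kt}$;
* nascent polymerase density: $\mu/v$ per nt of gene body.

The two decay estimators are

$$\mathrm{DR}_{\text{labeling}} \;=\; -\frac{1}{t}\,
  \ln\!\left(1 - \frac{\mathrm{RNA}_{4tU}}{\mathrm{RNA}_{total}}\right),
  \qquad t = 2\ \text{min},$$

using background-subtracted, spike-normalized gene-end signal, and

$$\mathrm{DR}_{\text{transcription}} \;=\;
  \frac{\text{gene-body pA$^-$ density}}{\text{total gene-end signal}},$$

which is $\propto k/v$ at steady state and therefore meaningful as a
*rank* (arbitrary units). The logarithm is natural, consistent with the
half-life conversion $k = \ln 2 / t_{1/2}$. A labeled/total ratio at or
above 1 (possible after noise and background subtraction) has no finite
first-order solution; such estimates are flagged non-finite and excluded
rather than clamped, and downstream summaries use finite estimates only.
A ratio of exactly 0 gives rate 0.

## Tunable parameters

| parameter | default | unit | why |
|---|---|---|---|
| labeling time | 2 | min | pulse length of the protocol; short enough to enrich nascent RNA |
| body trim | 200 | bp | keeps the TES-proximal pA+ cluster (and its spread) out of the body |
| end flank | 200 | bp | TES ± 200, a 401-nt window containing the natural 3'-end heterogeneity |
| spike extension | 300 | bp | spike features counted TSS → TES + 300 |
| mask windows | 6/18 | nt | strict rule: > 4 A and no C/T in 6 nt; relaxed: > 12 A in 18 nt |
| min MAPQ | 5 | — | operationalizes "uniquely aligned"; configurable, NH tag used when present |
| metagene bin | 10 | nt | resolution/smoothing compromise for sparse tracks |

"TES ± 200" is realized as the half-open window $[TES-200, TES+201)$,
including the TES base itself; inclusivity is not observable at the
resolution of the downstream statistics but is fixed and documented here.

## The A-mask

Oligo-dT primers anneal to genome-encoded A stretches, creating 3'-end
artifacts immediately upstream of them. A position is masked when the
RNA-strand sequence *downstream* of it (positions $p+1 \dots p+w$; the
reverse complement of the upstream genomic window on the minus strand)
has more than 4 A and no C/T within 6 nt, or more than 12 A within
18 nt. G and N are read literally as permitted non-A bases, and N never
counts toward any base class. A third upstream filter used elsewhere
against mismapping artifacts is deliberately not applied. Whether the
original rule included the candidate position itself in the window is
not recoverable; both behaviors are implemented
(`mask_rule(include_self = )`), with exclusion as the default because
the artifact model is dT annealing strictly 3' of the observed end.
Windows truncated by a chromosome end are evaluated on the available
bases. Masked positions are removed from tracks; region densities divide
by the *effective length* (length minus masked positions), which keeps
the density of a uniform signal invariant under masking.

## Background subtraction and the omission rule

The mock IP (unlabeled cells, same spike-in) measures nonspecific
carryover. Spike-normalized mock signal is subtracted positionwise from
labeled tracks, and aggregated mock counts from labeled feature counts.
Remainders ≤ 0 are *omitted*, not clamped: the position (or feature)
simply drops out, and the dropped deficit is tallied so that
$\mathrm{mass}(a) - \mathrm{mass}(b) =
\mathrm{mass}(\text{result}) - \text{dropped deficit}$ holds exactly.
Tracks use positionwise subtraction; region quantification subtracts
aggregated counts and applies the rule at the feature level.

## Normalization

Spike-in features are counted from TSS to TES + 300 and fed to the
standard median-of-ratios estimator: the per-feature reference is the
geometric mean across samples (computed in log space, over features with
all counts positive); a sample's size factor is the median ratio to that
reference. Because the reference moves when a library is rescaled, size
factors are defined up to a common constant — all downstream ratios
(decay rates, pA- derivation) are invariant to that constant, and the
exact scaling covariance holds for factor ratios. Median-of-even-counts
is taken in log space, matching the estimator's canonical
implementation.

## Splice junctions

EE reads have a block gap exactly matching an annotated intron, at least
2 aligned nt on each side, and no block overlapping any intron of the
TU; EI/IE reads cross an exon–intron (5'ss) or intron–exon (3'ss)
boundary contiguously with at least 2 nt on each side. Labels follow
transcript orientation, so the genomic left edge of a minus-strand
intron is its 3' splice site. A contiguous read spanning a short intron
entirely emits both EI and IE — each retained intron presents both
boundaries, which is also why the unspliced index is $(EI + IE)/2$.
Counting happens on raw alignments; size-factor scaling and mock
subtraction follow.

## Metagene matrices

Reference-point mode averages signal in fixed bins around an anchor
(TSS, TES, 3'ss); scale-regions mode rescales gene bodies onto a common
length (default 2 kb) by averaging the source positions that map to each
target bin under a linear coordinate map (no interpolation), with
unscaled flanks. Mass is conserved up to one bin's worth of signal,
which is tested. Profiles are the per-bin mean of $\log_2$ signal over
regions with positive signal; zero bins are treated as missing rather
than pseudocounted, because single-nucleotide 3'-end tracks are mostly
zero and any pseudocount would dominate the mean — a configurable
pseudocount exists for dense data. Bins outside the chromosome are
missing. Row sorting (by signal or length) never changes profiles, by
construction.

## The synthetic study

`sim_config()` defines a 50-gene panel (60% mRNA-like, 20% SUT-like,
20% CUT-like) with log-normal $\mu$ and class-specific log-normal $k$
(medians ≈ 0.08, 0.3 and 1.5 min$^{-1}$ — half-lives of minutes for
mRNAs, tens of seconds for CUTs), $v = 1500$ nt/min, a 2-min pulse,
5% mock carryover, ten spike-in features at 1% of library mass, a ±5 nt
geometric spread of mature ends around the TES, and 2 × 10^5 expected
reads per library — a desk-scale analogue of a shallow yeast experiment
chosen so the full suite runs in minutes. All randomness is seeded; a
fixed seed reproduces every artifact byte for byte.

Expected signals place mature mass $\mu/k$ (labeled: $\times(1-e^{-kt})$)
at the TES spread, uniform nascent density $\mu/v$ along bodies of
E-PAP-treated samples, mock tracks as carryover times the total track,
identical absolute spike signal everywhere, and a per-sample capture
efficiency multiplying the whole library. Labeled samples additionally
carry the same carryover contamination that the mock measures, so
background subtraction is exact in expectation. Decay intermediates —
spliced, exon-restricted pA- ends of the *old* (unlabeled) RNA pool at
a rate of $3 \times 10^{-4}$ of mature abundance per exonic nt — are the
one deliberately phenomenological component: they are what makes the
total sample's intron/exon pA- density ratio fall below 1 while the
labeled sample stays near 1, and give the total fraction its spliced
(EE-dominated) junction reads. In a 2-minute pulse essentially all decay
intermediates derive from pre-existing RNA, which is why they are absent
from the labeled-true component.

Poisson counting noise is applied per position with each library scaled
to the same expected depth, mirroring equal-depth sequencing;
per-library capture efficiency therefore shows up as differing spike
shares, exactly as in the real protocol. Simulated reads follow the
reverse protocol (alignment strand opposite the RNA, alignment 5' end at
the RNA 3' end); nascent molecules retain each intron until the
polymerase is 300 nt past the 3' splice site, so with 50-nt reads a
nascent read never presents a spliced junction.

Genome sequence is random with two interventions: deliberate A-tracts in
intergenic gaps (true positives for the mask), and a fixed C/G-bearing
pattern inside gene-end and spike-counting windows so that the A-mask
cannot, by sampling accident, delete mature 3'-end signal of the
synthetic study — body windows stay fully random, so masking inside
bodies (where effective-length correction applies) is exercised.

What the generator does *not* emulate: realistic yeast base composition,
TES read-through and alternative 3' ends beyond the ±5 spread,
overdispersed counting noise, TRAMP oligo-adenylation of pA- species, or
uridine-content-dependent labeling bias. Passing tests therefore
demonstrate the correctness of the computational contracts under a
first-order kinetic model, not robustness to every artifact of real
libraries.

## Numerical choices and degenerate inputs

* Coordinates are 0-based half-open everywhere internally; BED/bedGraph
  are native, GFF3 is converted at the boundary.
* bedGraph carries no strand, so stranded tracks are file pairs
  (`*_plus.bedgraph` / `*_minus.bedgraph`); reading decomposes
  multi-base lines to single nucleotides, writing re-merges equal runs,
  and the round trip is the identity.
* Tracks store strictly positive values; absent means zero. Subtraction
  results are recomputed positionwise on the union of stored positions.
* TUs not longer than the body trim have no body (omitted from body
  statistics, kept in end statistics). Intervals are clipped at
  chromosome bounds and never acquire negative length.
* snRNA/snoRNA decay can be quantified at the exact annotated mature
  3'-end position (`use_mature_ends = TRUE`) instead of the end region,
  reflecting their stable, non-adenylated mature ends.
* Spearman correlations use average ranks for ties, pairwise-complete
  rows of the log2 table, and require at least 3 complete pairs;
  p-values use the t approximation; the clustering distance is
  $(1-\rho)/2$ with complete linkage.
* The noiseless end-to-end identity holds to floating-point accuracy
  (~10^-13 relative), not bitwise, because normalization and subtraction
  reorder arithmetic; tests assert 10^-9.

## Interfaces

The package is tidyverse-shaped: tracks, annotations, quantifications
and manifests are tibbles; every user-facing function takes the data
frame first and pipes; `tidy()`/`glance()` methods cover the correlation
and run objects and `autoplot()` the correlation matrix and metagene
profiles. `inst/cli/ends3p.R` is a thin Rscript wrapper (subcommands
`simulate`, `mask`, `run`) for shell use; BAM input is supported through
an optional Rsamtools adapter, with BED12 as the canonical text
alignment format.

## Known limitations

Overlapping TUs are quantified independently and strand-specifically
with no signal apportionment. Background subtraction is plain
subtraction (no statistical model of the mock). The transcription-ratio
decay estimator assumes constant elongation speed across genes; genes
with strong pausing would distort its ranks. The simulator's directional
checks (intron/exon ratio, junction composition) are qualitative by
design: their effect sizes depend on the phenomenological intermediate
rate, which is fixed once, not fitted.
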