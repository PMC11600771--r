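---
title: "Insertion-capture SNV calling for rapid amplicon nanopore panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Insertion-capture SNV calling for rapid amplicon nanopore panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ampliSNV)
```

## The problem and the method

Intraoperative molecular stratification of CNS tumors hinges on a small set
of hotspot single-nucleotide variants — IDH1 R132, IDH2 R172, the TERT
promoter sites C228 and C250, H3F3A K27/G34, HIST1H3B K27, and BRAF V600.
Multiplex amplicon nanopore sequencing can deliver these calls while surgery
is still in progress, provided the per-read analysis is simple, streaming,
and robust to nanopore error.

ampliSNV implements the *modified-reference* (insertion-capture) calling
idea. For each marker, the reference used for alignment is the amplicon with
the variant base(s) **deleted**. A read spanning the site must then align
with an artificial insertion at the deletion junction, and the inserted
sequence *is* the read's allele:

* inserted sequence equals the wild-type allele → **WT**;
* equals a named mutant allele → **MUT** (with the variant's name);
* anything else — the wrong base, a longer string, or nothing at all —
  → **UNRECOGNIZABLE**.

The appeal over conventional pileup calling is symmetry: wild-type and
mutant reads are detected by the same mechanism (an insertion call), so the
wild-type evidence is captured explicitly rather than inferred from absence
of a variant.

A read is evaluated at every marker of the amplicon it aligns to — the two
TERT promoter sites, 22 bp apart on one amplicon, yield two independent
calls from each read.

## Per-marker quantities

With per-marker counts $n_\text{wt}$, $n_\text{mut}$ (per variant), and
$n_\text{unrec}$, the default variant allele fraction is

$$\widehat{\mathrm{VAF}} = \frac{\sum_v n_{\text{mut},v}}
      {n_\text{wt} + \sum_v n_{\text{mut},v} + n_\text{unrec}},$$

i.e. every assigned call is in the denominator. This is the convention under
which 55 mutant calls among 85 assigned reads report a VAF of ~65 %
(`marker_vaf()`). The estimator restricted to interpretable calls,
$\sum_v n_{\text{mut},v} / (n_\text{wt} + \sum_v n_{\text{mut},v})$, is
available as `marker_vaf(..., denominator = "called")`; see *Which
denominator, when* below.

## The pipeline

```{r pipeline, eval = FALSE}
panel <- cns_panel()                     # or load_panel("my_panel.json")
reads <- read_reads("run.fastq")         # arrival order preserved
res   <- call_reads(reads, panel)        # align -> extract -> classify
summary(res)                             # per-marker tallies and VAFs
plot(res)                                # streaming VAF trajectories
```

Internally each read is assigned to an amplicon and strand by a k-mer vote
(k = 13, 16 probe positions; exhaustive both-strand alignment against all
modified targets is the fallback when the vote is inconclusive), oriented,
and aligned to the modified target of every marker on that amplicon with a
local affine-gap aligner. The insertion observed within a tolerance of the
deletion junction is classified against the marker's allele dictionary.
Alignments can also be imported from PAF files carrying a `cs` difference
tag (`call_paf()`), and exported the same way (`write_paf()`).

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `match`, `mismatch` | +2 / −4 | local alignment scores |
| `gap_open`, `gap_extend` | −4 / −2 | a gap of length L costs 4 + 2L |
| `min_score_frac` | 0.4 | accept alignments scoring ≥ 0.4 of the perfect score |
| `flank` | 10 bases | aligned (match/mismatch) bases required on each side of the junction; reads failing it are *not callable* (dropped, not counted) rather than unrecognizable |
| `tol` | 2 bases | insertions within ± tol of the junction are attributed to it (aligners shift insertions inside repeats) |
| `width` (per marker) | 1 | number of deleted bases; multi-base codon markers remain expressible |
| `alpha` | 0.05 | significance level of the Welch test |

The alignment scores match common long-read mapper defaults. The flank
requirement exists so that clipped or barely-overlapping alignments do not
contribute junction evidence.

## Streaming statistics

`vaf_series()` tracks the running VAF of each marker against its cumulative
read count — read order, not wall-clock time, is the axis, so results are
reproducible from a FASTQ alone. Two replicate groups of such series are
compared with a Welch (unequal-variance, two-sided) two-sample t-test at
each point of a read-count grid (`threshold_scan()`): each replicate
contributes its own VAF at the last count at or before the grid point and is
excluded until it has accumulated that many calls. Two crossings are
reported: `n_first`, the smallest count with p ≤ α (the quantity used by the
read-count threshold experiments), and `n_stable`, the smallest count from
which significance holds at every later evaluated point. Welch was chosen
because the replicate groups of interest are small and unequal (2 vs 3 in
the motivating designs) and their variances differ by construction. When
both group variances vanish the p-value is defined as 0 for unequal means
and 1 for equal means.

No multiple-testing correction is applied across markers (each marker is
reported at its own per-marker α); scanning for a *first* crossing inflates
the nominal type-I rate, which the test suite bounds empirically rather than
corrects — with 3 replicates per group the observed null crossing fraction
is well under 0.15. `detection_limit()` wraps the scan over a grid of true
VAFs: the limit is the smallest simulated VAF whose replicates separate
significantly from the 0 % replicates; the wild-type replicate runs are
simulated once per marker and reused across the grid.

## The synthetic read simulator

The simulator stands in for the PCR + flow cell: it emits full-length
amplicon reads in arrival order, with

* per-amplicon abundance weights (a GC-rich amplicon can be down-weighted
  with `amplicon_weights(panel, down = "TERT")` to emulate the
  under-amplification of high-GC targets in multiplex PCR);
* per-marker true VAFs (`sample_profile()`, linear dilution mixing with
  `mix_profiles()` — a heterozygous 0.5 profile mixed 1:1 with wild type
  gives 0.25);
* independent per-base substitution (0.03), insertion (0.02) and deletion
  (0.03) errors — an R9.4-class nanopore profile, stated as a modeling
  assumption, not a measured value;
* random strand (reverse complement with probability 0.5) and a seed that
  makes runs byte-reproducible.

It does **not** model read fragmentation, chimeras, adapters, quality
scores, PCR duplicates, or signal-level effects. Passing tests on simulated
reads therefore demonstrate the calling logic and its statistics, not
robustness to every artifact of real flow-cell data.

The shipped `cns_panel()` uses deterministic *synthetic placeholder*
amplicons (489–680 bp, inside the realistic 489–1098 bp range and kept near
the lower end so that exact dynamic programming remains cheap at experiment
scale; the TERT amplicon is generated at ~78 % GC). Each hotspot carries its
canonical wild-type base, and the two bases on either side of every junction
are constrained to differ from both alleles so that the artificial insertion
cannot slide through a homopolymer run. Real panels do not always grant this
property — in repetitive junction context the attribution tolerance `tol`
does the work, and widening the deletion (`width` > 1) is the robust remedy.

## Numerical and degenerate-input choices

* Alignment ties are broken deterministically: higher score, then longer
  target span, then lexicographically smallest target id (`best_alignment()`).
* The pipeline uses a banded DP (half-width `max(50, 0.1 ×` read length`)`)
  for speed; it is validated against the full DP in the test suite and the
  exact full DP remains available (`band = 0`).
* A marker with no assigned calls reports VAF `NA` ("no data"), never a
  division error; empty FASTQ input yields a valid all-`no_data` report.
* An empty junction insertion (the allele base was lost to a deletion
  error) counts as UNRECOGNIZABLE — evidence of a covered, uninterpretable
  site — rather than being dropped.
* Grid points where either replicate group has fewer than two usable
  replicates are skipped, not interpolated.

## Which denominator, when

Under the default error model about 30 % of junction-covered reads are
UNRECOGNIZABLE. Two mechanisms dominate, both intrinsic to reading an
allele off a single noisy read: a deletion error within ~2 bp of the
junction makes the score-optimal alignment absorb the artificial insertion
into mismatch columns (one mismatch costs no more than an
insertion-plus-deletion pair, and the two interpretations are genuinely
ambiguous at the edit level), and an insertion error near the junction
merges with the allele into a longer, unrecognized string.

This loss hits wild-type and mutant reads symmetrically. Consequently:

* the **all-calls** denominator (default) matches the field's reporting
  arithmetic for assigned reads, but under-reports the *template* VAF by
  the unrecognizable share;
* the **interpretable-call** denominator (`denominator = "called"`) is the
  consistent estimator of the template fraction — in the package's dilution
  experiment a true 25 % VAF is recovered at ~25 % by the interpretable
  estimator.

The dilution-recovery experiment therefore reports the interpretable-call
estimator, while tallies, reports, trajectories and the worked 55/85
example use the default convention. Both are always available from the same
tally.

## Experiment sizes

The packaged experiments run at desk scale on one core: the read-count
threshold experiment uses 3 + 3 replicate runs of 500 reads per marker over
a grid of every 5 reads; the dilution recovery uses 2,000 reads; the
detection-limit experiment uses the VAF grid {0, 1, 2, 5} % with 3
replicates × 1,000 reads for each of the 8 marker variants. These sizes are
the package's validation conditions; all are parameters of the exported
functions.

## Known limitations

* Markers are substitution hotspots; indel variants at the site are not
  classified (they surface as UNRECOGNIZABLE).
* No quality-aware calling: base qualities are ignored end to end.
* The two TERT sites are called independently; reads are not phased.
* Sequential significance scanning is reported uncorrected (see above).
* The k-mer preselection assumes amplicons are mutually distinguishable at
  k = 13; pathological panels (near-duplicate amplicons) fall back to
  exhaustive alignment, which is slower but safe.
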