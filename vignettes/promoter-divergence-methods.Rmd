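---
title: "Methods: promoter divergence scanning, indel clustering and selection tests"
author: "promdiv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: promoter divergence scanning, indel clustering and selection tests}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its statistical machinery:
the models, the conventions behind every tunable parameter, what the
synthetic-data generator does and does not emulate, and the design choices
made where the methodology was genuinely open.

## 1. Event coding of multi-species promoter alignments

The input is a gapped alignment of one promoter region across several
closely related species (five in the motivating *melanogaster*-subgroup
setting), with one record designated the reference.  Three binary channels
are derived per alignment column:

* **base changes** — column is 1 when at least one non-reference species
  carries a non-gap base different from the reference's non-gap base.
  Columns where the reference (or the differing species) shows a gap are 0
  here; `N` is missing data and never creates an event.  This is the
  conservative choice for ambiguous bases, on which the methodology is
  otherwise silent.
* **indels** — every maximal gap run in every record (including runs in
  the reference, which represent insertions in other species) contributes
  exactly one event at its 5′-most column.  Runs touching column 0
  register at column 0; there is no 5′-flanking column to prefer.
  Coincident starts across species collapse to a single 1 (the channel is
  binary); counting per species instead would change the G test's `n` but
  not its logic, and the binary convention matches the 0/1 coding of the
  channels.
* **all changes** — the position-wise OR of the two.

Divergence is measured **relative to the reference record** by default.
The alternative reading — any pairwise difference among the species —
is available as `comparison = "any_pair"`; the reference mode is the
default because downstream displays ("changes from the reference") and
the synthetic generator's star phylogeny are both reference-centric.

Coordinates are 0-based half-open throughout.  Each column maps to an
ungapped reference coordinate (`refCoord`); columns that are gaps in the
reference share the preceding reference position.  TSS anchoring assigns
each column a signed offset in reference coordinates, negative upstream,
offset 0 at the first transcribed base; for minus-strand genes upstream
lies at larger genome coordinates, so the sign flips.  How the TSS column
was located inside a cross-species alignment is not derivable from the
alignment itself, so the operation takes the column (or the reference
coordinate) as explicit input.

## 2. Sliding event scores, d, and group contrasts

The sliding event score is `Se(i) = Σ events over [i − h, i + h]` with
`h = 5` by default (an 11-position window).  Two conventions matter:

* **Reference grid.** Se is computed per reference position, not per
  alignment column: insertion columns are first collapsed (binary OR) onto
  the preceding reference base.  This keeps every gene's promoter window
  at exactly 350 positions regardless of how many insertion columns its
  alignment happens to contain.
* **Edge truncation.** Windows are truncated at the profile ends rather
  than dropped, so N stays fixed.

The promoter window is [−380, −30) — half-open, which gives exactly the
350 nucleotides of the TATA-distal region; "−30 to −380" inclusive would
give 351.  `Se^C` is the arithmetic mean of all control-group Se values
pooled across genes and positions in that window, and

d = 100 · #{Se > Se^C} / N,

with strict inequality: ties count as not-above, following the strict
"greater than" definition.  N is interpreted as the number of scored
window positions (350 per gene, pooled across a group's genes), not the
number of non-zero events — under the 0/1 coding every position is an
event slot, and pooling matches group-level quantification.  The
alternative — compute d per gene, then average — is available via
`perGene = TRUE` in `regionStats()`; the chi-squared counts stay pooled
either way.

Significance versus the control is a 1-df Pearson goodness-of-fit of the
observed (above, not-above) counts against the control group's own
proportion, `p` from the chi-squared distribution.  The Bonferroni family
defaults to the number of group-vs-control tests within one channel (the
smallest natural family — e.g. four subcomplexes against one control) and
is exposed as a parameter, since no larger family is dictated by the
construction.  A control proportion of exactly 0 or 100% leaves an
expected cell of zero and is reported as a degenerate-expectation error
rather than a fabricated statistic.

## 3. The G-function clustering test

For `n` sorted event positions on `L` columns (1-based sites `s_j`),

G_j = j/n − s_j/L,  ΔG_j = G_j − G_{j−1},  G_0 = 0,

so evenly spaced events give G ≡ 0 and clusters give runs of positive ΔG.
The virtual origin G_0 = 0 makes a leading cluster detectable.

**Global statistic.** The methodology tests "differences of G between
events" without fixing how gaps combine; we use the maximal rise of G over
any event interval, `max over 0 ≤ j ≤ k ≤ n of (G_k − G_j)` — a scan/KS-type
one-sided statistic that dominates any single-gap ΔG and directly yields
the reported stretches.  Allowing `j = k` floors the statistic at 0, which
also gives the natural `max(G_1, 0)` for a single event.

**Null and p-value.** Each Monte Carlo replicate draws `n` distinct sites
uniformly from the `L` columns (100,000 replicates by default; tests use
fewer) and recomputes the statistic; `p = (1 + #{null ≥ obs}) / (1 + B)`
— the add-one estimator, which can never return 0.  For small designs an
exact null by full enumeration of all `choose(L, n)` configurations is
available (`exact = TRUE`).  The replicate loop is vectorised: batches of
sorted site rows are drawn by rejection (exact, since duplicate rows are
redrawn) and the running-minimum scan runs column-wise over the batch.

**Stretches.** When the global p ≤ 0.05 the interval achieving the
maximal rise, `[s_j + 1, s_k]` in 1-based sites, is reported; further
non-overlapping intervals are accepted greedily in order of G-excess while
their excess exceeds the null 95th percentile.  The exact stretch-calling
rule behind published cumulative-G figures is not specified in detail
anywhere we could follow, so this greedy rule is a declared design choice;
per-gap ΔG p-values (against the null maximal single-gap ΔG) are attached
for transparency.  No analytic p-value approximation is attempted.

## 4. McDonald–Kreitman tests and α

Per gene the 2×2 table [[Pn, Ps], [Dn, Ds]] is tested with a two-sided
Fisher exact test (the direction of departure is reported separately via
the table odds ratio, so "positive selection" calls require a Dn/Ds
excess), with Benjamini–Hochberg FDR across genes — the specific FDR
procedure is not dictated, BH is the standard default.  Degenerate tables
(an all-zero row or column) return p = 1 by convention.

α = 1 − (Ds·Pn)/(Dn·Ps) is undefined when `Dn = 0` or `Ps = 0` and is
flagged `NA` rather than crashing; pooled ("concatenated") α sums the four
counts across genes first.  The bootstrap contrast draws `k = 30` genes
with replacement `B = 100` times per group, takes each draw's pooled α,
and compares the two α samples with an unpaired t test (Student's
equal-variance variant by default, Welch selectable).  Draws with
undefined α are redrawn with a bounded retry budget, keeping B fixed, and
redraw events are reported.  The genome background is a user-supplied
table collection; no online database is queried.

## 5. Conservation profiles and d^P

Per-base scores (bedGraph or wiggle; read and written with `rtracklayer`)
are anchored into vectors of exactly 1300 positions spanning offsets
−1000…+299 around each TSS, strand-resolved (minus-strand genes read
genome coordinates descending).  Genes with any missing position in the
window are omitted and reported, never imputed.

Group mean profiles are per-offset arithmetic means.  The promoter
contrast has two parts: an unpaired t test on per-gene window means over
[−380, −30), and

d^P = 100 · #{p < p^C} / N

with `p^C` the control group's promoter-window mean and strict inequality
(ties count as not-below).  The chi-squared contrast mirrors the d
construction — observed (below, not-below) counts against the control
group's own below-threshold proportion — i.e. count-based, consistent with
the Se analysis, rather than a test on the percentages themselves.  The
"control" role is an explicit argument (a genome-wide cohort when
contrasting a focal complex against the genome).  Scores are taken as
given; no conservation model is re-fit from alignments.

## 6. The synthetic-data generator

The generator emulates the three external inputs with known ground truth.

**Alignments.** A star phylogeny: an ungapped random reference of
`seqLength` nucleotides (default 2000, matching a ±1 kb TSS window), each
other species derived independently by per-site substitutions
(`subProb`, default 0.02) and indel events (Poisson, `indelRate` per kb,
default 2; geometric lengths with `indelLenP = 0.5`, minimum 1;
insertions and deletions equally likely).  A hotspot triple
`(start, end, multiplier)` scales the indel rate inside a window.  The
star topology is deliberate: all downstream statistics use per-column
difference from the reference, so tree shape is out of scope, and no
substitution-model or branch-length machinery is simulated.  The
geometric length law is a stand-in — the empirical indel length spectrum
of real promoters is not modelled.

Two properties are guaranteed by construction and verified by test:

* **Exact recoverability.** Every planted event maps to exactly one
  detectable 5′ gap-run start.  Events keep a 1-position buffer within a
  species; across species only two point collisions are excluded (two
  insertions sharing an anchor, and an insertion anchored exactly at a
  deletion start) — a case analysis shows every other cross-species
  adjacency, including overlapping deletions in different records, leaves
  all 5′ starts detectable.
* **Placement fidelity.** A colliding event is moved to the nearest
  feasible position (alternating sides), not redrawn.  Redrawing would
  condition placements on empty space and measurably thin dense regions —
  at a 10× hotspot the planted in-hotspot fraction drops by about 0.01,
  an order comparable to the sampling error of the calibration tests —
  whereas the nearest-slot shift preserves the target distribution up to
  a few nucleotides.

**Conservation tracks.** 1300-position vectors at `baseMean` with
Gaussian noise and an optional subtracted `promoterDrop` on a stated
sub-interval (default the TATA-distal window).  `profilesToTrack()` lays
cohorts onto genome coordinates with alternating strands so the
bedGraph/anchoring path is exercised round-trip.

**MKT counts.** Ps ~ Pois(meanPs), Pn ~ Pois(ratio·meanPs),
Ds ~ Pois(meanDs), Dn ~ Pois(meanDs·ratio/(1 − α)); the pooled α of a
cohort converges to the target by construction.

What the generator does **not** emulate: phylogenetic correlation between
species (each derived record is independent), alignment error
(alignments are consumed as given, there is no realignment or quality
filtering), heterogeneous substitution processes, autocorrelated
conservation scores, or linkage between the MKT counts and the simulated
sequences.  Passing tests therefore demonstrate the correctness and power
of the statistics under clean, known-truth conditions — not robustness to
alignment artefacts or model misspecification in real genomes.

## 7. Reference parameter set and test problem sizes

`promdivDefaults()` collects the reference values in one place: Se
half-window 5; promoter window [−380, −30); event anchor span
[−1000, +1000); conservation window [−1000, +300); 100,000 Monte Carlo
replicates; bootstrap k = 30, B = 100; significance level 0.05.

The test-suite simulations are sized to give stable checks at interactive
cost: Monte Carlo nulls of 1000–2000 replicates for calibration loops
(hundreds of designs), 100–500 alignments for recovery and hotspot
checks, cohorts of 200 genes per group for the conservation power checks,
and 5000 genes per group for α recovery.  The acceptance script reruns
the same analyses from a single seed.

## 8. Known limitations

* The binary channels discard multiplicity: a column diverged in four
  species counts as one event, and two species' indels sharing a 5′
  column count once.
* The G test conditions on the observed `n`; it has no power when events
  are few, and its p-value resolution is 1/(B + 1).
* d and d^P depend on the choice of control group; with a degenerate
  control proportion the chi-squared contrast is intentionally
  unavailable.
* The pipeline consumes TSV/FASTA/bedGraph-scale inputs; bigWig-backed
  random access is out of scope.
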