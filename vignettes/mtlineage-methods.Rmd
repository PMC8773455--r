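---
title: "mtlineage: methods, conventions and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{mtlineage: methods, conventions and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtlineage)
```

This vignette is the package's own account of its science: the models and
conventions each stage implements, the tunable parameters and their
defaults, what the synthetic-data generator does and does not emulate, and
the design choices made where the design was genuinely open.

## 1. Coordinates, windows, and variant notation

All variants are reported against a 16,569-bp circular reference in
1-based coordinates (in real work the revised Cambridge Reference
Sequence, rCRS). The control region spans the replication origin, so
windows may wrap: the full CR is `coord_window(16024, 576)` (1,122
positions), HVS1 is nps 16024–16365, and the cross-dataset comparison
window is the 546-bp segment nps 16024–16569. Membership tests and window
lengths use modular arithmetic throughout; closed intervals and 1-based
positions follow the PhyloTree/EMPOP convention (the literature never
spells this out, but the forensic community's notation presupposes it).

Calls use the forensic token grammar: `16189C` (substitution), `16193.1C`
(first inserted base after np 16193), `249del`. A profile may not carry
two calls with the same `(position, kind, insertion index)`; parsing and
formatting round-trip canonically, with variants ordered by position.

## 2. Variant calling

`call_variants()` performs minimal-edit (unit-cost) global alignment of a
sample sequence to the reference window and converts the alignment to
calls. Two conventions make calls reproducible across tools:

* **Indel placement.** Among the (often many) optimal alignments through a
  homopolymer run, indels are reported at the 3′-most position of the run
  — the EMPOP/forensic standard. Implementation: any one optimal
  alignment is computed, then every gap is bubbled rightward through
  score-equivalent single-column swaps until it cannot move; this reaches
  the unique 3′-most placement regardless of which optimal alignment the
  aligner returned.
* **Divergence guards.** Sequences whose length differs from the window
  length by more than 20 bp, or whose edit distance exceeds a ceiling
  (default 60), are rejected with an error naming the sample rather than
  silently profiled; control-region reads that far from the reference are
  essentially always tracking or orientation artifacts.

The dynamic program itself is delegated to `Biostrings::pairwiseAlignment`
with a unit-cost scoring scheme (match 0, mismatch −1, gap −1); a
hand-banded R implementation was considered and dropped, since the C
aligner is both faster and better tested, and the package's contribution
is the call conventions, not the DP. An exhaustive enumeration of all
optimal alignments serves as the oracle in the test suite.

IUPAC two-base codes in the input (point heteroplasmies) are carried
through as the derived base of a substitution call;
`mask_heteroplasmies()` rewrites them to `N` before any haplotype-level
comparison, and is idempotent.

## 3. Haplogroup classification

A motif tree (TSV: `node_name`, `parent_name`, `motif`) assigns each
branch the mutations expected on the path into that node. The cumulative
motif of a node applies branch motifs sequentially from the root: a later
expectation at a position overrides an earlier one, a reversion token
`16189!` cancels the inherited expectation at np 16189, and a second
reversion at the same position re-adds it (PhyloTree's back-mutation
convention).

`classify()` scores every node against a masked profile:

$$\mathrm{score} = \frac{\mathrm{matched} - w\cdot\mathrm{missing}}
{\mathrm{matched} + \mathrm{private}}$$

where *matched* counts expected calls observed (an observed `N`
substitution matches any expected substitution at its position), *missing*
counts expectations inside the profile window that are absent, and
*private* the observed calls no expectation explains. Ties break to the
deeper node, then lexicographically. Two properties motivate this form:

* Expectations are restricted to the profile window, so control-region-only
  data are never penalized for coding-region motif positions they cannot
  show; the missing-weight `w` (default 0.5) softens true absences, which
  is how real CR data tolerate occasional back-mutations.
* `matched + private` equals the total observed-call count for *every*
  node, so the ranking is governed by the numerator alone: adding a
  private mutation that no node expects can never reshuffle the ranking.

This scoring rule is the package's own design (published pipelines
delegate to external classifiers whose internal measures differ); the
weight is exposed, and the exhaustive-scoring brute force in the test
suite pins the argmax semantics. The empty profile scores 0 at the root
and negatively everywhere expectations exist, so a reference-identical
sequence classifies to the reference haplogroup — the correct degenerate
behavior.

Macro-haplogroup assignment maps haplogroup names onto 18 coarse labels
(A, B, D, G, JT, L3\*, M\*, M7, M8, M9, N1, N2, N9, R\*, R0, R9, U, X) by
longest-prefix rules (`M7b` → M7, not M\*; `H1j` → H through R0), and each
macro label carries a geographic origin class: WEu = {JT, N1, N2, R0, U,
X}, EAs = {A, B, D, G, M\*, M7, M8, M9, N9, R\*, R9, L3\*}. The origin of
the paragroups L3\*, M\* and R\* is genuinely unsettled in the literature;
they default to EAs purely so the partition is total, and the whole table
is a user-replaceable TSV.

## 4. Diversity and distance statistics

Site filtering follows two regimes, both exposed:

* **Complete deletion** (default for *S*, Hd, π): a column is dropped if
  *any* sequence carries a gap, `N`, or ambiguity there — matching the
  "excluding gaps and ambiguous sites" practice of DnaSP-style summaries.
* **Pairwise deletion** (default for p-distance): each pair is compared
  over the columns where both are base-called — MEGA's default.

With `n` sequences over `L` usable columns:
`Hd = n(1 − Σ pᵢ²)/(n − 1)` over exact row-string identity (after masking,
`N` is a literal character, consistent with the sharing module), and
`π = Σ_{i<j} d_ij / (C(n,2) L)` with no additional `n/(n−1)` correction —
the common DnaSP output definition. The all-pairs sums are computed by
per-column haplotype counting and per-base indicator matrix products, so
country-scale datasets (millions of pairs) stay exact but vectorized.
Note the small-sample correction places Hd slightly *above* its large-`n`
limit `1 − Σ pᵢ²`; duplicating every row moves Hd from the `n/(n−1)` to
the `2n/(2n−1)` correction of the same spectrum.

Between-population distance matrices use the mean pairwise p-distance over
all cross-group pairs; populations under a minimum size (default 30, the
conventional exclusion threshold for comparison groups) are dropped with a
logged warning, and the diagonal is zero by convention.

## 5. Ordination

PCA operates on population × macro-haplogroup relative-frequency rows,
column-centered and by default *not* variance-scaled (frequencies share a
unit); scaling is a flag because the two tools commonly used for such
plots (R's `prcomp` and spreadsheet add-ons) differ in their defaults.
Compositional transforms (CLR/logit) are deliberately not applied — the
analysis tradition this package follows uses raw frequencies. Classical
MDS is Torgerson's double centering `B = −½ J D² J` with eigenvalues
truncated at zero (a warning reports truncation; an all-non-positive
spectrum is an error). Both methods fix the arbitrary axis signs by making
the largest-magnitude loading (PCA) or coordinate (MDS) positive, so runs
are bit-reproducible.

## 6. Haplotype sharing

Two samples share a haplotype iff their canonical keys — the masked
variant set restricted to the comparison window, in canonical order — are
byte-identical. `N` is literal: masking happens *before* sharing, and
wildcard `N`-matching would break transitivity of key identity. The
phrase "total haplotypes in each paired group" is ambiguous (per group or
union? samples or distinct haplotypes?); the package resolves it as
*distinct haplotypes per group*, computes both directional ratios
`|A∩B|/|A|` and `|A∩B|/|B|`, and reports their mean as the headline
symmetric value — all four numbers are returned and written to the
long-format output so any alternative reading can be reconstructed.
When every haplotype's origin class is well defined, the EAs-restricted
and WEu-restricted shared counts add up to the overall count, which the
test suite asserts.

## 7. Ancient-lineage tracing

Records are dated in signed calendar years (−1000 = 1000 BCE; years-BP
inputs convert with the 1950 datum at load time; radiocarbon uncertainty
is ignored, matching how such comparisons are usually presented). A
lineage matches a record when the record's haplogroup equals it or is
nested inside it — phylogenetically when a motif tree is supplied, else
by name prefix with a token-boundary guard exploiting PhyloTree's
alternating letter/digit nomenclature (`H5a1a` extends `H5a1`; `H51` does
not extend `H5`).

`trace_lineage()` then classifies presence in a longitude band:

* band default 85–125 °E ("Mongolia and nearby regions") — a reading of
  the shaded-longitude device used in published arrival maps, fully
  configurable since no numeric band is standard;
* cutoff default −1000 (the post-Bronze-Age timeline);
* the earliest in-band matching record decides the status
  (pre-cutoff presence / post-cutoff arrival / absent);
* among matching records west of the in-band arrival, the earliest-dated
  (ties broken westernmost) is the precursor; a post-cutoff arrival whose
  precursor strictly predates it by 20–40° of longitude to the west is
  flagged route-consistent. Whether that 20–40° statement is a rule or a
  post-hoc observation is unknowable from the narrative it summarizes, so
  both bounds are parameters.

## 8. The synthetic world

`simulate_modern()` draws, per sample: a haplogroup from the population's
frequency vector; the reference window edited by the cumulative motif;
`Poisson(private_rate)` private substitutions; with probability
`heteroplasmy_prob`, one base replaced by a two-base IUPAC code. Defaults
are chosen once as the field's realistic regime and not revisited:

* `private_rate = 1` — control-region haplotypes typically carry a few
  positions beyond their haplogroup motif; one extra substitution per
  sample on average reproduces that texture without drowning the motifs;
* `heteroplasmy_prob = 0.005` — point heteroplasmies are seen in roughly
  half a percent of forensic-grade control-region profiles;
* the demo layout mirrors a country-wide survey: 20 province groups plus
  an "unspecified" group, sizes summing to 2,420, EAs-dominated with WEu
  enrichment rising westward to ≈22% overall.

Private mutations are substitutions only and are drawn uniformly from
window positions *outside* every motif-defining site of the packaged tree.
Both restrictions are deliberate: substitution-only noise keeps the
alignment stage exactly invertible (indel calling is exercised by
dedicated fixtures instead), and avoiding motif sites keeps the generating
haplogroup identifiable, which is what makes "classification recovers the
truth" a meaningful closed-loop test rather than a statement about luck.
No hotspot model and no coalescent genealogy are simulated — the
statistics under test do not depend on them, and a green closed loop
therefore establishes correctness of the *pipeline*, not realism of the
mutation process. With `shared_fraction` set, every sample receives a
unique tag substitution (so distinct-haplotype counts equal sample counts)
and the configured fraction of the second population's haplotypes is
copied verbatim from the first — making the planted sharing ratio an exact
target rather than a random variable.

`simulate_ancient()` realizes per-lineage trajectory specs (optional
in-band record, optional western precursor) and records the implied truth
status. The packaged narrative fixture plants 13 post-cutoff arrivals
(6 route-consistent) and 7 pre-cutoff presences; its in-band record for
T2g belongs to the sub-lineage T2g1a, so tracing the parent finds the
consistent trajectory while tracing the sub-lineage finds no matching
precursor — a deliberate nested-lineage case.

## 9. Packaged stand-ins

The repository is self-contained and offline, which forces two synthetic
stand-ins, both labelled as such in their filenames and documentation:

* `rcrs_synthetic.fasta` — a deterministic 16,569-bp sequence with
  human-mtDNA-like base composition, regenerated bit-identically by
  `build_synthetic_rcrs()`. It is *not* NC_012920.1; real analyses must
  supply the true rCRS.
* `minitree_subset_synthetic.tsv` — a ~100-node motif tree covering the
  18 macro-haplogroups and the named lineages discussed above. Branch
  positions are synthetic except where the narrative fixes them: the
  postulated HV13b1 branch carries nps 1654, 9377, 11152 (coding) and
  16184, 16291 (control region); the U5b1c2 branch carries only np 9110,
  which is why that lineage is invisible at control-region resolution and
  classification falls back to U5b1c there (its parent wins on the
  window-restricted score).

Because motifs are synthetic, numeric results on packaged data
(diversities, sharing ratios) characterize the synthetic world only; the
pipeline's correctness is established by the oracle-equivalence and
closed-loop recovery tests, not by resemblance of any packaged number to a
published one.

## 10. Numerical and degenerate-input choices

* Score ties in classification break to depth then name, making batch
  classification order-independent and reproducible.
* `1e-9` in the score denominator only serves the zero-observed-call case;
  it never affects ranking (the denominator is constant across nodes).
* A pair of sequences with zero comparable columns under pairwise deletion
  is an error naming the pair, not an `NaN`.
* MDS eigenvalues are compared against `max(eig) * 1e-12` to decide
  positivity, avoiding sign noise on exactly-embeddable inputs.
* Windows are validated on construction; restriction to a non-nested
  window is an error rather than a silent intersection.
* Sequences shorter than the analysis window by more than 20 bp are
  rejected (the HVS1-at-least rule), not partially profiled.

## 11. Known limitations

* The classifier is motif matching with a fixed penalty; it does not
  reimplement Kulczynski-weighted engines (Haplogrep) or string-alignment
  classifiers (EMPOP SAM2), and published pipelines report occasional
  disagreement even between those two — no single ground truth exists for
  edge cases.
* No BAM/FASTQ handling and no raw-read calling; input starts at
  assembled control-region sequences or variant tables.
* π and Hd printed by different software differ in deletion mode and indel
  handling; both modes are implemented, but reproducing any specific
  published value requires knowing which mode produced it.
* Most-parsimonious tree building, Bayesian coalescent dating, skyline
  plots, and map rendering are out of scope.
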