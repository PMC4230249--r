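---
title: "Pseudo-testcross linkage mapping and BAC-end sequence analysis with seriomap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pseudo-testcross linkage mapping and BAC-end sequence analysis with seriomap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

seriomap builds sex-specific genetic linkage maps for an outbred F1 family by
the pseudo-testcross strategy, and carries the companion analyses that
typically surround such a map in a marker-development project: genome-length
and map-coverage estimation, BAC-library and end-sequence survey arithmetic,
microsatellite (SSR) mining from masked end reads, and Oxford-grid synteny
analysis of BLAST hit tables. This vignette explains the statistical model
behind each stage, the tunable parameters and their defaults, what the
synthetic-data generators do and do not emulate, and the numerical and design
choices a maintainer should know about.

```{r setup}
library(seriomap)
```

## The mapping model

The mapping panel is a single outbred family: two wild parents and their
progeny (the study scale is 90 offspring). Because the parents are outbred
and their own parents are unavailable, neither linkage phase nor grandparent
origin is known. The pseudo-testcross device treats each parent separately:
at every marker where a parent is heterozygous, its meioses segregate 1:1
exactly as in a backcross, so each progeny can be coded by which of the two
parental alleles it inherited (`to_backcross()`, codes A/H). Markers
heterozygous in both parents contribute to both maps; progeny whose
transmitted allele cannot be deduced (e.g. an a/b offspring of an a/b x a/b
marker) are coded missing for that marker.

**Phase folding.** Since phase is unknown, the A/H labelling is arbitrary per
marker. All pairwise statistics therefore fold the recombinant count to
`min(r, n - r)` before estimating the recombination fraction
`theta = r / n`. The price is a small upward bias in theta for unlinked
pairs (folding truncates at 0.5) and a factor-two multiple-testing cost in
the grouping stage; the alternative -- guessing phase -- has no information
to draw on in a two-generation design.

**Two-point LOD.** For a pair with `n` jointly informative meioses and
folded recombinant count `r`, the backcross LOD is

    LOD = r log10(theta) + (n - r) log10(1 - theta) + n log10 2,

with the limit `n log10 2` at `theta = 0`. Pairs with LOD at or above the
grouping threshold (default 4.0) become edges of a linkage graph whose
connected components are the linkage groups (single linkage, so sparse
chains of markers group correctly).

**Ordering.** Within a group, the marker order is chosen to minimize the
total number of recombination events over adjacent intervals -- the
parsimony objective that double-recombinant checking implies, since every
misplaced marker manufactures spurious double recombinants. Groups of up to
8 markers are solved exactly by enumeration; larger groups are seeded by
greedy nearest-neighbour chaining from every start plus a spectral seed (the
Fiedler-vector order of the linkage-similarity Laplacian, a 1-D embedding
that avoids the chaining pathologies of greedy construction), then refined
by 2-opt segment reversals, or-opt relocation of 1-3 marker segments, and a
ripple pass that exhaustively permutes every sliding window of 5, iterated
to a joint local optimum. On simulated study-scale groups this matches the
exhaustive optimum whenever the exhaustive search is feasible.

**Map curation.** Two curation steps run inside `linkage_map()` by default;
both are the automated counterpart of the manual map checking that
interactive mapping tools expect their users to perform:

* *Double-recombinant correction* (`correct_doubles`): a call whose code
  differs from both flanking informative calls is, at dense marker spacing,
  almost always a genotyping error, and each such error inflates the map by
  two spurious recombination events. With a 0.5% per-call error rate and
  ~1.8 cM true spacing, theta for an adjacent pair is inflated from ~0.018
  to ~0.028 -- a ~50% map-length inflation if left uncorrected. Flagged
  middle calls are set to missing and the group is re-ordered on the cleaned
  data. True double crossovers within two short adjacent intervals are rare
  (of order theta squared), so the bias introduced by removing genuine
  events is at the percent level and conservative (it shortens the map).
* *Weak-joint splitting* (`split_weak`): with ~700 markers there are over
  2 x 10^5 unlinked marker pairs, and the folded null probability of a
  LOD >= 4 score at n = 90 is about 1-2 x 10^-5, so a handful of spurious
  edges per analysis is *expected*; single linkage then welds two
  chromosomes into one chimeric group. Because the ordering stage places
  such a chimera as two internally coherent blocks joined by one interval
  with essentially no linkage, the chimera is detectable and reversible:
  any ordered group is split at adjacent intervals whose two-point LOD
  falls below the grouping threshold, split parts are re-ordered, and the
  check is repeated until stable. The split threshold deliberately reuses
  the grouping LOD -- no additional tuning constant is introduced.

**Distances.** Adjacent recombination fractions are converted with the
Kosambi map function `d = 25 ln[(1 + 2 theta)/(1 - 2 theta)]` cM, the
convention of the fish-mapping literature this package follows. Adjacent
fractions are capped at `theta_max = 0.49` (a finite cap keeps positions
finite when a pair carries no linkage information); co-segregating markers
sit at identical positions rather than being dropped. A *framework marker*
is operationalized as the first marker at each distinct map position, i.e.
one representative per resolvable locus; for reproduction of published
summary tables, framework counts are taken from the table itself and never
recomputed, since the original criterion is not derivable from the data we
have.

**Segregation distortion.** Every marker is tested against 1:1 transmission
with the d.f. = 1 chi-square goodness of fit
`chi2 = (n_A - n_H)^2 / (n_A + n_H)` without continuity correction, at
alpha = 0.05. At n = 90 the discreteness of the binomial makes the exact
size of this test about 4.5-4.8% rather than 5.0%; the calibration test in
the suite accounts for binomial sampling error around that level.

## Genome length and coverage

From per-group summary rows (markers, framework markers, length), the
average framework interval is `d = sum(length) / sum(m - 1)`, where a group
with m framework markers contributes m - 1 intervals. Two genome-length
estimators are provided: L1 adds `2d` to every group (terminal markers do
not reach chromosome ends), and L2 inflates each group by `(m + 1)/(m - 1)`;
a group with m <= 1 has no defined inflation factor and contributes its
observed length unchanged. Map coverage is `c = 1 - exp(-2 d n / L)` with
`n` the total framework count. Using framework markers (not all markers)
for both `d` and `n` is the only convention under which the published
summary table this package ships as a worked example is internally
consistent, and it is the statistically defensible one: co-segregating
markers at one position add no independent coverage. All derived cells are
computed at full precision and rounded to two decimals only for printing;
reproduction tolerances are ±0.02 because published totals may have been
summed from pre-rounded cells.

`library_stats()`, `bes_stats()` and `genome_size_from_cvalue()` (978 Mbp
per pg) cover the survey arithmetic around a BAC library: insert counts,
total insert length, fold genome coverage, mean read length and the genome
fraction sampled by qualified reads.

## SSR discovery

End reads arrive vector- and quality-masked (lowercase or N); only
uppercase A/C/G/T counts as evidence. A read qualifies with more than
100 bp of unmasked sequence (`min_len = 101`). `find_ssrs()` reports every
maximal perfect tandem array with unit length 1-10 and at least
`min_copies` complete copies, at its primitive unit (an AC run is never
also an ACAC run), with strand- and rotation-invariant canonical naming
(CA, TG, GT and AC all belong to AC/GT). The default `min_copies = 7` reads
the "more than six repeats" selection rule strictly; the inclusive reading
is one argument away. Compound arrays are reported as separate adjacent
motifs, and `pick_representative()` then takes the longest in bp (ties:
leftmost) per read; `clone_marker_selection()` implements the SP6-first,
T7-fallback convention of end-sequencing projects. Coordinates are 1-based
inclusive throughout, the R convention.

## Orthology and Oxford grids

BLAST tabular hits are post-processed per query: hits are ranked by e-value
(ties by bit score), zero e-values are floored at 1e-180, and the top-three
e-value-ratio rule decides orthology: if the second or third hit overlaps
the top hit's query interval by at least one base and `e1/ek > 1e-3`, the
assignment is *unclear* and rejected; otherwise the top hit's chromosome is
accepted. Only the rank-1 hit can ever be accepted; ranks 2-3 act purely as
vetoes. Accepted assignments are cross-tabulated by linkage group into an
Oxford grid with the conventional highlighting (more than 10/7/5 pairs:
red/yellow/blue), and `grid_relationships()` classifies one-to-one and
one-to-two patterns using the blue cutoff (>5, configurable) as the signal
threshold. Overlap is assessed on query coordinates only; requiring
subject-side overlap as well is a stricter variant the source material does
not specify.

## Synthetic data: what it emulates, what it does not

`simulate_cross()` generates the mapping study's assumed data-generating
process: Mendelian 1:1 transmissions, meioses as a no-interference Poisson
crossover process on the Haldane scale, fully informative markers by
default (mixable informativeness classes), genotyping errors as random
transmission flips, and missingness as random blanking. Defaults are the
study conditions: 24 chromosomes of 40-60 cM, 29 markers per chromosome,
90 progeny, 0.5% error, 2% missing. Two deliberate mismatches with real
data: crossover interference is *not* simulated even though distances are
reported in Kosambi cM (the estimator is evaluated like-for-like, and at
~2 cM spacing the Haldane/Kosambi discrepancy is below 2%), and allele
dropout, null alleles and scoring artefacts beyond random flips are not
modelled. Passing recovery tests therefore demonstrates correctness of the
estimator under its own assumptions, not robustness to structured artefacts
of real gels.

`generate_ssr_reads()` produces i.i.d. background at a target GC with
planted perfect arrays; planted flanks are broken so an array cannot extend
by chance, and an optional cleanup pass mutates accidental background
arrays (scanning one copy below the detection threshold, for margin) so
planted-truth recovery tests are exact. `generate_blast_hits()` plants a
linkage-group-to-chromosome relation and engineers decoy hits on either
side of the rejection ratio. Every generator takes a mandatory seed and
returns machine-readable truth.

## Test and acceptance scales

The suite exercises the full study scale once: 24 x 29 markers x 90
progeny (~700 markers, ~240,000 marker pairs), grouped at LOD 4.0, which
runs in roughly 10-15 s. Order agreement with truth is measured by Kendall
tau after resolving co-segregating blocks by the true order, since markers
at identical estimated positions carry no order information; at 90 meioses
about a fifth of adjacent pairs co-segregate, and an occasional single
displaced marker in a recombination desert caps the worst per-chromosome
tau near 0.86-0.94 across seeds -- a resolution limit of 90 meioses, not of
the search (the parsimony optimum then ties or beats the true order's
objective). Map-length recovery is assessed on the genome total: a single
chromosome's length estimate has a sampling standard deviation near 15% at
this scale (28 intervals, each theta estimated from ~86 meioses), while
the total is stable to a few percent, with a small net downward bias
(Kosambi compression of Haldane truth plus removal of genuine double
recombinants) that sits well inside the 15% band. Calibration of the
distortion test uses 1,500 independently simulated single-marker
chromosomes; ordering-oracle equivalence uses 200 random groups of 3-8
markers against exhaustive enumeration; the orthology rule is checked
against a brute-force evaluator on 1,000 random hit sets.

## Known limitations

* Two-generation panels cannot recover phase; all linkage evidence is
  phase-folded, and maps for the two parents are built independently
  (no sex-averaged map).
* Ordering is parsimony-based two-point analysis, not multipoint maximum
  likelihood; at 90 meioses, co-segregating blocks are unordered and
  single-marker displacements into long gaps can survive because they are
  genuinely parsimony-optimal.
* The distance between consecutive markers comes from the pairwise theta
  only; no re-estimation against flanking markers is attempted.
* Framework-marker identification is a position-uniqueness proxy; published
  framework counts are inputs, not outputs.
* SSR detection is perfect-repeat only; interrupted or compound
  microsatellites are reported as separate arrays.
* The weak-joint split heals chance merges only when the chimera orders as
  two clean blocks; a merge whose bridging marker sits mid-group could
  escape it (not observed at study scale in practice).
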