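# seriomap

Sex-specific genetic linkage maps from a single outbred F1 family, plus the
companion analyses of a marker-development project: genome-length and
map-coverage estimation, BAC-library and end-sequence survey statistics,
microsatellite (SSR) mining from masked end reads, and Oxford-grid
comparative synteny from BLAST hit tables. The package grew out of
linkage-map construction for yellowtail (*Seriola quinqueradiata*), a
farmed marine fish whose breeding programs need dense SSR maps for QTL
mapping, and it is written for geneticists building maps for any outbred
aquaculture or wildlife species where inbred lines do not exist.

## What it computes

**Pseudo-testcross mapping.** In a cross of two outbred parents, each
parent's heterozygous markers segregate 1:1 through its own meioses, so
maternal and paternal maps are built independently in backcross form. With
grandparents unknown, phase is unknown, and the recombinant count of a
marker pair is folded to r' = min(r, n − r) before estimating
θ̂ = r'/n. Linkage is scored with the standard two-point backcross LOD

    LOD(θ̂) = r log₁₀ θ̂ + (n − r) log₁₀(1 − θ̂) + n log₁₀ 2 ,

markers are grouped by single linkage at LOD ≥ 4.0, each group is ordered
by minimizing total adjacent recombination events (exhaustive ≤ 8 markers,
seeded local search above), single-marker double recombinants are blanked
as genotyping errors, chance-merged groups are split at internal joints
whose LOD falls below the grouping threshold, and adjacent θ̂ are converted
to Kosambi centimorgans, d = 25 ln[(1 + 2θ)/(1 − 2θ)].

**Genome length and coverage.** From per-group rows (markers, framework
markers m, length): average framework interval d = Σlength / Σ(m − 1);
genome length L₁ (add 2d per group) and L₂ (inflate each group by
(m + 1)/(m − 1)); coverage c = 1 − e^(−2dn/L) with n the framework count.

**SSR discovery.** Qualified reads (> 100 unmasked bp), GC content,
maximal perfect tandem arrays of 1–10 bp units with ≥ 7 copies at their
primitive unit and strand-invariant canonical name (AC/GT, AAT/ATT, ...),
longest-motif representatives, and SP6-first/T7-fallback clone selection.

**Orthology.** BLAST tabular post-processing with the top-three
e-value-ratio rule (reject when a lower hit overlaps the top hit and
e₁/eₖ > 10⁻³), Oxford grids with red/yellow/blue highlighting at > 10/7/5
orthologous pairs, and one-to-one / one-to-two relationship calls.

**Simulators** for crosses (Poisson/Haldane meiosis with genotyping error
and missingness), masked reads with planted SSR motifs, and hit tables
with planted synteny — each returning machine-readable truth, so every
pipeline stage is testable without downloads.

## Worked example

```r
library(seriomap)

sim <- simulate_cross(n_chromosomes = 4, markers_per_chromosome = 12,
                      n_progeny = 90, seed = 42)
map <- linkage_map(sim$genotypes, parent = "dam")
map
#> Pseudo-testcross linkage map (female meioses)
#>   48 markers in 4 linkage groups (LOD >= 4.0), 90 progeny
#>   total length 188.05 cM; 1 distorted marker(s) at alpha = 0.05; 23 double-recombinant call(s) blanked

summary(map)
#> Linkage map summary (female):
#>  group n_markers n_framework length_cM
#>    LG1        12           7     37.23
#>    LG2        12          11     50.21
#>    LG3        12          11     34.67
#>    LG4        12           9     65.95
#> Total: 48 markers, 38 framework, 188.05 cM in 4 groups
```

Each row is one linkage group: marker count, framework markers (one per
resolvable position), and Kosambi length. The 23 blanked calls are
isolated double recombinants — at this marker density almost certainly the
simulated 0.5% genotyping errors, whose removal keeps the map length near
truth. These rows feed the genome-length estimators:

```r
est <- build_map_summary(summary(map))
#> d = 5.53 cM, L1 = 232.30 cM, coverage 83.6%
```

and the library arithmetic works standalone:

```r
library_stats(110592, 0.71, 140700, genome_size_from_cvalue(0.7))
#> BAC library: 110,592 clones, 71% with insert -> 78,520 clones
#>   mean insert 140.7 kb; total insert 11.0 Gb; 16.1x (~16x) a 685 Mb genome
```

The published yellowtail per-group map table ships with the package
(`yellowtail_map_rows("female")` / `"male"`) as a worked input for the
estimators; `build_map_summary()` on those rows reproduces its printed
L1/L2 totals, average intervals and coverage percentages to within
rounding.

## Layout

- `R/` — genotype model and backcross conversion; two-point/grouping/
  ordering/Kosambi machinery; the `linkage_map()` fitter with
  print/summary/plot methods; map statistics; SSR scanning; orthology and
  Oxford grids; simulators.
- `inst/extdata/` — the published per-group map summary rows (TSV).
- `vignettes/seriomap-methods.Rmd` — models, assumptions, parameter
  choices, limitations.
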