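---
title: "Models and methods behind gbskit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind gbskit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gbskit)
```

`gbskit` implements a genotyping-by-sequencing (GBS) discovery workflow for
predominantly selfing crops — the setting of inbred line collections and
recombinant inbred line (RIL) mapping populations in species such as
cultivated oat, an allohexaploid (2n = 6x = 42) where reference-free
tag-based genotyping and aggressive filtering against homoeologous
confounding are the norm. This vignette explains the models, the tunable
parameters and their defaults, the numerical choices, and what the
synthetic-data generator does and does not emulate.

## SNP calling from sequence tags

GBS reads collapse into *tags*: unique 64 bp sequences each representing a
pile of identical reads at a restriction site. Without a reference genome,
SNPs are discovered as pairs of tags that differ at a small number of
positions.

* `pair_tags()` links tags supported by at least `min_tag_count` reads
  (default 10) that differ at no more than `max_mismatch` bases (default 1),
  and discards tags in mismatch networks of more than two members. The
  network filter is implemented as connected components of the mismatch
  graph with components of size other than two dropped — a deliberate
  simplification of the full network-topology rules used by tag-pair
  pipelines; it keeps exactly the unambiguous reciprocal pairs.
* `fisher_population_filter()` is the population-level test: for a putative
  allelic pair, lines are tallied as carrying tag 1 only, tag 2 only, both,
  or neither, and a **two-sided Fisher exact test** of independence is
  applied. In an inbred population a true single-locus bi-allelic SNP makes
  the two tags strongly negatively associated (nearly every line carries
  exactly one of them), so independence is rejected; tags drawn from
  different loci (e.g. homoeologues) co-occur freely and are not. The
  default threshold is p < 0.001. Sidedness is a design choice: allelic
  pairs sit in the extreme negative-association tail, which a two-sided
  test detects identically, and two-sided is the conventional default.
  Lines carrying neither tag are counted in the "neither" cell by default
  (`count_empty_as_neither`), since absence of both tags is itself
  informative about coverage, not allelic state; a flag excludes them.
* `call_genotypes()` scores a line heterozygous when both tags are observed
  and the minor tag exceeds the `error_tolerance` fraction (default 0.02)
  of reads; at or below the tolerance the minor reads are attributed to
  sequencing error and the call is homozygous for the majority tag. The
  boundary is deliberately strict (`>`), so a 1-in-100 minor read remains a
  homozygous call. All calls are co-dominant.
* `merge_catalogs()` maintains a cumulative nomenclature: SNPs are named by
  a zero-padded sequential index in insertion order, records are unified
  across catalogs when their strand-canonical context (lexicographic
  minimum of the bracketed context sequence and its reverse complement)
  and alleles agree, and merging is idempotent. Strand canonicalisation is
  our choice; tag pipelines do not fix a strand.

## Population-specific filtering

`locus_stats()` reports per-locus completeness (fraction of lines with a
call), minor allele frequency (heterozygotes contribute one copy of each
allele — standard diploid counting), and heterozygosity among called lines.
`filter_loci()` applies inclusive thresholds; the package default mirrors
the within-population mapping filter (completeness ≥ 50%, MAF ≥ 35%,
heterozygosity ≤ 8%). The 8% ceiling corresponds to the residual
heterozygosity expected of an F5 RIL population once sequencing error and a
little outcrossing are allowed for; 13% plays the same role for F4
material. One unit of `depth_index` is 2×10⁶ good barcoded reads per
sample — the average share of one 95-plex sequencing lane — so 1.16×10⁶
reads score 0.58.

## Linkage: phases, placement and de novo maps

Recombination fractions are estimated by **simple recombinant counting**
over lines with homozygous calls at both loci (`rf_matrix()`).
Heterozygous calls are excluded: in near-inbred populations they are rare,
disproportionately error-prone, and ambiguous for a two-locus recombination
count. No RIL-generation correction is applied to the raw fraction by
default, matching the simple-count convention; apparent fractions above 0.5
are meaningful — they flag a locus scored in the wrong parental phase.

`assign_phase()` orients progeny calls so that "A" is the parent-1 allele
wherever both parents have informative homozygous calls; loci with missing
or monomorphic parental data are emitted in both phases under `_p1`/`_p2`
names. `correct_phases()` then counts, for every locus, linked loci in the
same phase (apparent rf < 20%) versus opposite phase (rf > 80%), flips
loci with more out-of-phase than in-phase matches, and eliminates loci that
remain conflicted after flipping. Ties — including completely unlinked loci
with no counted neighbour — are kept unchanged, because flipping without
evidence is unjustified. Exactly one copy of each both-phase twin pair
survives.

`place_markers()` saturates a framework map: each candidate is anchored to
the two framework loci with the smallest apparent rf **across all
populations** (a minimum over populations, not a pooled estimate; ties are
broken by larger informative-line count, then locus name). Interior
anchors give the interpolated position

d(candidate) = d(f1) + (d(f2) − d(f1)) · rf₁ / (rf₁ + rf₂),

which always lies between the anchors. When the nearest anchor is terminal
and the candidate is farther from the second anchor than the anchors are
from each other, the candidate is placed distal to the end of the group at
1 cM per 1% recombination — the small-distance equivalence of all map
functions — so positions below 0 cM occur off the start of a group and are
preserved by the map writers.

`denovo_map()` groups loci as connected components of the rf < 0.25 graph,
drops loci more than 15 cM (Kosambi) from every other locus and groups of
fewer than three, orders each group by a depth-first traversal of the
minimum-spanning tree of rf distances from one end of the tree diameter,
and reports adjacent distances through the Kosambi map function
d = 25 ln((1+2r)/(1−2r)). The MST heuristic replaces a full ordering
algorithm; it recovers locus order well on clean simulated groups, which is
what the tests certify, and makes no claim to optimality on noisy real
data. The simulator itself uses the Haldane (no-interference) model per
meiosis; Kosambi is used only for reporting distances, so the two roles
never mix.

## Structure, kinship and LD

`vanraden_kinship()` computes the realized relationship matrix from
−1/0/1-coded genotypes, mean-imputing missing calls per locus, centering by
twice the allele-frequency deviation from one half, and scaling by
2Σp(1−p). `pca_structure()` mean-imputes, standardizes markers (a flag
disables scaling) and reports eigenvalues, coordinates, percent variance
explained, and the first four PCs rescaled per component to [0, 1] as
structure covariates. `ld_regress()` implements the pre-PCA correction for
marker dependency: each standardized marker is replaced by its
least-squares residual on up to `k` preceding markers within `ldlimit`
Morgans (default 0.001 M, i.e. 0.1 cM, interpreted as map distance in the
smartpca convention); `k = 0` is a no-op.

Four LD estimators are provided per locus pair (`ld_records()`):

* `r2` — squared Pearson correlation of allele dosages;
* `r2_s` — correlation of OLS residuals on the scaled PC covariates;
* `r2_v` — correlation after whitening by K^(−1/2) about the GLS mean
  (kinship-corrected);
* `r2_sv` — whitened GLS residuals on the covariates (both corrections).

K^(−1/2) is taken by eigendecomposition with an eigenvalue floor of 1e−8,
after adding a 1e−6 ridge when K is not positive definite. Missing
genotypes are mean-imputed for the corrected estimators so that one
whitening transform serves all pairs.

LD decay is modelled with two curves in C = 4·Ne·c (c in Morgans):
the Sved drift–recombination equilibrium E[r²] = 1/(1 + C), and the
Hill–Weir drift–mutation curve with sample-size adjustment

E[r²] = [(10+C)/((2+C)(11+C))] · [1 + ((3+C)(12+12C+C²)) / (n(2+C)(11+C))].

Both are fitted by unweighted nonlinear least squares on pairs with map
distance ≤ 30 cM, and each fit reports Ne, its standard error, and the
distance at which the fitted expectation reaches r² = 0.1, solved
numerically (`ld_d01()`; for Sved the closed form is 900/(4Ne) cM and the
numerical root agrees to 1e−8). Two numerical points worth noting: `n` in
the Hill–Weir adjustment is the number of inbred **lines** (340 for a
340-line panel), which is the parameterisation under which the model's
distance-at-0.1 values round-trip the reported effective population sizes;
and the Hill–Weir curve does not decay to zero but to its 1/n sampling
floor (0.00294 at n = 340), which the tests assert explicitly.

## Germplasm diagnostics

`allele_match_dissimilarity()` scores d_ij = 1 − (1/L) Σ (m_l/2) with m_l
the number of matching alleles (2 identical, 1 het vs hom, 0 opposite
homozygotes) over the L loci called in both lines — L varies per pair, and
pairs with no shared informative locus are flagged undefined rather than
guessed. `upgma()` performs average-linkage clustering with ultrametric
node heights equal to **half** the between-cluster dissimilarity (so two
lines at d = 0.2 join at height 0.1, and Newick leaf depths equal half the
cophenetic dissimilarity); ties are broken by lexicographic label for
reproducibility. `match_unknowns()` pairs unknown samples with known lines
at d ≤ 0.05 by default. `verify_cross()` separates selfed seed from a true
cross: the per-call discordance rate between progeny and the putative
parent is compared with a 1% scoring-error tolerance, a heterozygote vs
homozygote difference counting as discordant because true F2 progeny are
diagnosed chiefly by segregating heterozygosity.

## What the synthetic-data generator emulates

`sim_config()` holds the study conditions: a 21-linkage-group consensus
map; six RIL populations with sizes 98, 98, 53, 52, 53, 52 at F6 by
default (the spread of F4–F8 sizes that motivates the design); an
outcrossing rate of 1% per line per generation (exposed as a free
parameter — the heterozygosity-threshold reasoning implies some
outcrossing without stating a rate); a per-read tag mis-assignment rate of
0.002; and the depth model. All randomness derives from one integer seed:
each simulator seeds its own stream as `rng_seed + base + 1000·stream`,
with a fixed `base` per simulator (map 0, RIL 1, panel 2, reads 3) and a
caller-supplied `stream` for replicates, so identical configurations are
bitwise reproducible.

RIL populations are simulated from an F1 by repeated selfing with
crossovers drawn per interval from the inverse Haldane map function per
meiosis; residual heterozygosity at F_k is (1/2)^(k−1) in expectation.
Diversity panels draw inbred founders with a U-shaped Beta(0.5, 0.5)
allele-frequency spectrum rescaled to [0.02, 0.98] — most variants rare, as
in real germplasm collections, and the reason the panel-size experiment
shows its rise-then-plateau — and build each family by selfing an F1
between two founders from a shared pool for four generations, giving a
coancestry gradient (families sharing a founder are intermediate) without
strong discrete structure. Pedigree-expected kinship is recorded as truth.
Note that the default founder pool of `max(2, n_families)` lets two
families draw identical founder pairs when `n_families` is small; tests
that require separable families pass `n_founders` explicitly.

Read counts per line and locus are Poisson with mean
`depth_index · reads_per_locus_unit` (default 3 reads per locus at depth
index 1, chosen so that sub-unit depth indices produce the substantial
missingness that motivates completeness filtering), split between the two
allele tags by the true genotype and flipped by the error rate; zero reads
become missing calls. Poisson rather than negative-binomial coverage is a
simplicity choice; overdispersion is left as an extension hook.

The generator does **not** emulate homoeologous confounding (beyond what
the network and Fisher filters are designed to remove), linked-read error
structure, per-sample depth heterogeneity, centromeric recombination
suppression, or crossover interference. Passing tests therefore certify
the statistical machinery under the stated models, not robustness to every
artefact of real polyploid GBS data.

## Problem sizes and test design

The test suite runs everything at desk scale, chosen so the full suite
completes in well under a minute: heterozygosity calibration uses 10⁵
line-locus draws (20,000 lines × 5 loci) at F4 and F5 with a ±1-point
tolerance; the Fisher filter is checked exhaustively against a
hypergeometric enumeration for all 46,255 admissible 2×2 tables with
N ≤ 30 and for type-I control on 10⁵ simulated null tag pairs over 50
lines; phase-correction recovery uses 100-marker, 100-line populations
over three seeds with ten planted flips each; placement accuracy uses 500
candidates against a 5-group, 100-framework-locus map and three 100-line
populations (median absolute error observed well under the 2.5 cM bound);
decay-model recovery uses 2,000 pairs with Gaussian noise (sd 0.05) at
Ne ∈ {20, 100}; and the depth experiment uses a 53-line population with 80
loci. On that last fixture the locus inventory saturates: counts rise
monotonically with depth up to index ~1.2 and then sit at a plateau, a few
loci below the ceiling at high depth because accurate coverage exposes
residual heterozygosity to the ≤10% heterozygosity filter. The tests
assert the rising limb, the nesting of completeness thresholds, and that
the plateau stays within 10% of the ceiling — the shape a saturating
inventory should show, with the unbounded-inventory rise of real data
available only at scales beyond a fixture.

## Known limitations

Placement interpolates against exactly two anchors and inherits their
error; it is a positional approximation, not a re-estimated consensus map.
The MST ordering heuristic can transpose tightly linked loci. The
population-level Fisher filter assumes inbred material — in outbred or F2
populations both tags co-occur in heterozygotes and the independence test
loses its meaning. The corrected-LD estimators assume the kinship matrix
is estimated from enough markers to be treated as known. The demultiplexer
is a reference implementation for key-file validation and depth
accounting, not a high-throughput tool.
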