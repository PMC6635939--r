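---
title: "Methods: phylogeographic inference from single-locus haplotype data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phylogeographic inference from single-locus haplotype data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`haplogeo` implements the standard analysis stack for intraspecific
phylogeography of a non-recombining locus (mitochondrial COI, ribosomal
ITS spacers): haplotype collapsing and diversity, frequency- and
distance-based population differentiation, spatially constrained group
search, haplotype networks, demographic-history inference from the site
frequency spectrum and the mismatch distribution, and distance-based
DNA-barcoding identification at the population level. This vignette
records the estimators, conventions and design choices behind each
stage, and what the synthetic-data generator does and does not emulate.

## Data model

An alignment is a matrix of equal-length, uppercase IUPAC nucleotide
strings with unique sample ids; a population map assigns each sample to
a population, each population to a region, and each population to one
sampling site in decimal degrees. Two deletion policies coexist on
purpose:

* **Pairwise deletion** for distances and nucleotide diversity: each
  sequence pair is compared over the columns where both carry an
  unambiguous base. This keeps the most information per pair.
* **Complete deletion** for haplotype collapsing: only columns with no
  ambiguity code or gap in *any* sequence are retained. Pairwise-deletion
  identity is not transitive, so haplotype membership defined that way
  would not be an equivalence relation; complete deletion makes it one.

Sites variable only through ambiguity codes or gaps are not counted as
polymorphic, matching the behaviour of the common desktop tools for
these statistics.

## Distances

The Kimura two-parameter distance is computed from the transition and
transversion proportions P and Q as d = −½·ln(1 − 2P − Q) − ¼·ln(1 − 2Q).
Pairs for which either logarithm is undefined are *flagged as saturated*
and propagated as missing, never silently dropped; summaries report how
many pairs they excluded. Raw difference counts are used wherever a
mutation-step scale is wanted (AMOVA, mismatch distributions, networks).

## Diversity

Haplotype (gene) diversity uses Nei's unbiased estimator
h = n(1 − Σp²)/(n − 1) with sampling variance

V(h) = 2/(n(n−1)) · { 2(n−2)[Σp³ − (Σp²)²] + Σp² − (Σp²)² }.

Nucleotide diversity is the mean over unordered pairs of the per-pair
proportion of differing sites. Both operate equally on sequence-derived
catalogs and on printed count tables (`catalog_from_counts()`), which is
how the bundled 23-population COI survey table is analysed without any
sequence download.

## Differentiation: HS, HT, GST, NST

Following the Pons–Petit framework with Nei–Chesser small-sample
corrections: HS is the unweighted mean of per-population unbiased
diversities; HT = 1 − Σp̄² + HS/(ñs) with p̄ the unweighted mean
frequency vector, ñ the harmonic mean sample size and s the number of
populations; GST = (HT − HS)/HT. NST applies the identical functional to
distance-weighted diversities v = ΣΣ δ_kl p_k p_l with δ the raw
per-site differences between haplotype sequences, so when all
inter-haplotype distances are equal NST collapses to GST *exactly* — a
property the test suite asserts.

Two estimator subtleties worth knowing:

* On fixed, frequency-identical populations the GST point estimate is
  slightly **negative**, because HS is corrected per population while
  HT mixes in a plug-in pooled term. The estimator is unbiased around
  zero under multinomial resampling (also asserted by test), and small
  negative GST values are a familiar sight in the output of comparable
  programs.
* The phylogeographic-structure test permutes haplotype identities on
  the distance matrix (the PERMUT convention): GST is invariant, and the
  p-value is the add-one fraction of permutations with NST − GST at
  least the observed value. Standard errors are delete-one-population
  jackknives; a permutation distribution cannot provide them because it
  is degenerate for GST.

## AMOVA, pairwise FST, SAMOVA, Mantel

Molecular variance is decomposed from squared distances. For haplotypic
data the raw difference count *is* the squared Euclidean distance of the
one-hot site embedding, so counts enter the decomposition as-is;
continuous metrics are squared. Variance components come from the usual
unbalanced moment equations; negative components are retained in sums
and flagged rather than truncated, because silent truncation biases the
fixation indices. Permutation schemes are level-appropriate: individuals
among all populations (FST), individuals among populations within groups
(FSC), whole populations among groups (FCT); p-values use (b+1)/(B+1).

SAMOVA searches for the K-group partition of populations maximizing FCT
by simulated annealing over *geographically contiguous* partitions.
Contiguity is read from the Gabriel graph of the sampling sites under
great-circle distance — deterministic and parameter-free, and switchable
off to reproduce non-spatial behaviour. The annealing defaults
(t0 = 0.05, geometric cooling 0.95, 400 proposals per restart, 25
restarts, best-of-restarts) were chosen once for reliability at the
scale of a few dozen demes; on exhaustively enumerable worlds (≤ 8
demes) the search recovers the global optimum, which the test suite
checks against an enumeration oracle that scores candidates with the
independent `amova()` code path. Whether FCT rises with K is a property
of the data, not the algorithm: it increases on stepped
isolation-by-distance structure and can decrease past the true K on
clean two-clade structure; the tests cover both regimes.

The Mantel statistic is the Pearson correlation of lower triangles with
row/column permutation of one matrix, one-tailed by default.

## Median-joining networks

The network starts from the ε-relaxed minimum spanning network (an edge
is feasible iff its weight is within ε of the minimax path weight
between its endpoints, which at ε = 0 is exactly the union of all
minimum spanning trees) and iteratively adds consensus (median) vectors
of linked triplets when a star through the median is strictly cheaper
than the triplet's own spanning links. Median vectors left with degree
below three are pruned; raw hamming distances obey the triangle
inequality, so pruning cannot disconnect the network. Two deliberate
simplifications keep the construction deterministic: triplet columns
with three distinct states resolve to the central node's state rather
than spawning multiple quasi-medians, and ties are broken by fixed node
order. ε defaults to 0, the usual choice when no tolerance is published.
A star-likeness diagnostic (maximum node degree / number of observed
haplotypes) is reported to support expansion interpretations without
claiming a test.

## Demography

**Tajima's D** uses the textbook constants; significance is the
two-tailed fraction of neutral constant-size coalescent simulations,
conditioned on n with θ̂ = S/a₁, whose |D| reaches the observed value.
**Fu's Fs** is ln(S′/(1−S′)) with S′ = P(K ≥ K_obs | θ = θπ) under the
Ewens sampling formula, computed with log-space unsigned Stirling
numbers; its p-value is the fraction of simulations with Fs at most the
observed value (strongly negative Fs is the expansion signal, so the
test is left-tailed).

The **mismatch distribution** is fitted to the sudden-expansion
expectation

F_j = F̂_j(θ₁) + e^{−τ(θ₁+1)/θ₁} Σ_{i≤j} τ^{j−i}/(j−i)! [F̂_i(θ₀) − F̂_i(θ₁)],

with F̂ the geometric equilibrium distribution. The SSD surface is
multimodal, so fitting is a coarse grid over (τ, θ₀, θ₁) followed by
Nelder–Mead on log-scale parameters with the θ₀ ≤ θ₁ constraint built
into the parameterization. τ and θ₁ carry hard caps at small multiples
of the observed difference range: beyond them the SSD surface is flat
(the parameters are indistinguishable from infinity), an unbounded
search can run away to astronomical values, and the parametric
bootstrap would then simulate absurdly diverse data. Goodness-of-fit p-values are parametric
bootstraps: data re-simulated under the fitted model (coalescent with an
instantaneous size change at τ̂/θ̂₁ of ancestral/current ratio θ̂₀/θ̂₁),
refitted, statistic ≥ observed. Raggedness follows Harpending's
convention with an appended zero class — definitions differ across
software, so the same convention is applied to observed data and
bootstrap replicates alike.

Expansion times use t = τ/(2u), u = μ·k·g. The bundled reference
analysis uses k = 586 sites with μ ∈ {1.15, 1.77}×10⁻⁸ substitutions
site⁻¹ year⁻¹ and g = 1 year; by default k is taken from the analysed
alignment's length.

## Barcoding identification

Minimum distance (MD) assigns a leave-one-out query to the group of its
nearest reference; ties across groups are *ambiguous*. Best close match
(BCM) additionally rejects queries whose nearest reference exceeds a
threshold, by default the 95th percentile of within-group distances.
Leave-one-out itself is deterministic, so "replication" is bootstrap
resampling of the query set (size N, with replacement); the report
carries the mean success rate over replications and a normal
approximation interval mean ± 1.96·SD of the replication rates, labelled
as such. Ambiguous and unidentifiable queries count as failures in the
headline rate; the full outcome breakdown is always reported. The
barcoding gap is declared positive only when the smallest between-group
distance exceeds the largest within-group distance.

## The synthetic-data generator

`simulate_dataset()` draws a structured-coalescent genealogy for an
island model with two groups of demes (group-dependent migration rates,
optional instantaneous size change) and mutates it under a finite-sites
K2P-style model (transition probability κ/(κ+2)), so reverse and
parallel substitutions occur — necessary for realistic haplotype
collapsing and for median vectors to matter in networks. Time is scaled
so that a panmictic constant-size population has expected pairwise
difference count θ, and an expansion at coalescent time T corresponds to
a mismatch-scale expansion time τ = θ·T. The truth record (θ, migration
rates, T, size ratio, τ, deme→group map, seed) is always emitted, so
tests never re-derive ground truth from outputs.

The two-refugium preset reproduces the bundled survey's sampling design:
23 demes with the published sample sizes and coordinates, split into the
ten westernmost (longitude ≤ 108.3°E) versus the remaining thirteen
populations — the published analysis states a 10/13 southwest/east split
without listing members, so longitude rank is our reconstruction. The
remaining preset values are a stated world chosen once, not tuned:
θ = 3 per deme (a few within-deme differences, as observed for COI),
strong within-group gene flow (m = 5) against strongly restricted
between-group flow (m = 0.05, deep divergence between refugia), a
species-wide expansion at T = 0.5 with ancestral/current ratio 0.05
(recent, strong growth producing star-like clusters), 586-bp sequences,
κ = 5.

What the generator does *not* emulate: recombination and gene
conversion (relevant for nuclear ITS), selection, mutation-rate
heterogeneity along the sequence, sequencing error, and sampling-date
structure. A green test on simulated data therefore establishes that the
estimators recover the signal their model assumes — not that any
particular empirical dataset satisfies those assumptions.

## Numerical conventions

* All permutation/bootstrap p-values use the add-one rule
  (b+1)/(B+1) and so never return zero.
* Every stochastic entry point takes a `seed`; equal seeds give
  bit-identical results, including file outputs (the pipeline expands
  one master seed deterministically per stage).
* Default permutation and replication counts follow the reference
  analysis (1,000 for differentiation, 10,000 for AMOVA-family
  significance and neutrality tests, 1,000 mismatch bootstraps, 500
  identification replications); the test suite and examples run reduced
  counts, stated inline, purely for runtime.
* Comparisons against permuted statistics use a 1e−12 slack so ties
  count as extreme, keeping p-values conservative.

## Known limitations

* K2P saturation makes distances undefined for extremely divergent pairs;
  such pairs are excluded (with a logged count) rather than imputed.
* The Ewens-based Fs becomes ±∞ when S′ hits 0 or 1 numerically; the
  value is returned as infinite and flagged rather than clamped.
* SAMOVA is a stochastic search; for K near the number of populations,
  or with a sparse contiguity graph, restarts should be increased.
* The sudden-expansion fit assumes a single expansion; bimodal mismatch
  distributions from deep population splits will fit poorly (large SSD),
  which is the intended diagnostic behaviour, not a failure mode.
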