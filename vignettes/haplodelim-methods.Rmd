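---
title: "Methods: gene-tree species-delimitation statistics and their synthetic benchmarks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gene-tree species-delimitation statistics and their synthetic benchmarks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope and model

`haplodelim` evaluates a putative species-level taxonomy against a
single-locus gene tree. The unit of analysis is the *haplogroup*: the
set of tree tips assigned to one putative species. All tree statistics
are functionals of patristic distance — the sum of branch lengths on
the unique path between two tips — computed on the input tree exactly
as given: the tree is treated as rooted (no re-rooting), polytomies
and zero-length branches are allowed, and distances inherit whatever
units the branch lengths carry (substitutions/site for an ML
phylogram; Bayesian consensus trees may carry a different scale, which
is why the same taxonomy can yield within-group distances an order of
magnitude apart on two trees of the same data — the statistics are
comparable *within* a tree, and ratios are comparable across trees).

Numeric internal-node labels in the newick input are read as nodal
support. Whether they are bootstrap percentages or posterior
probabilities is declared by the caller (`support_kind`), never
auto-detected: the two scales overlap numerically and misreading one
as the other silently corrupts the support column. Categories follow
the conventional thresholds: bootstrap ≥ 75 strong, > 50 and < 75
moderate, ≤ 50 negligible; posterior ≥ 0.95 significant, otherwise
negligible.

## Per-haplogroup statistics

For focal haplogroup $g$ with members $M(g)$, $|M(g)| = n_g$:

- $\mathrm{Intra}(g) = \binom{n_g}{2}^{-1} \sum_{i<j \in M(g)} d(i,j)$,
  `NA` when $n_g = 1$;
- $\mathrm{Inter}(g) = \min_h \overline{d}(g, h)$ over other
  haplogroups $h$, where $\overline{d}$ averages all cross pairs; the
  minimizing $h$ is reported as the *closest* haplogroup. Exact ties —
  which genuinely occur on ultrametric coalescent trees whenever two
  candidate groups coalesce fully before joining the focal lineage —
  are broken towards the lexicographically smallest name, with a
  warning, so results are reproducible and order-independent;
- $\mathrm{Av}(g)$ = mean patristic distance from
  $\mathrm{MRCA}(M(g))$ to each member tip;
- singleton conventions: Intra, the ratio, Av, strict P ID and the
  MRCA support are all `NA` for $n_g = 1$ (a single tip has no
  within-group structure and its MRCA is itself); liberal P ID is
  still estimated. Column means exclude `NA` — nothing is imputed.

## The P ID Monte-Carlo estimator

P ID (strict) is the probability that a new, unknown member of $g$
falls *within* the clade of $g$; P ID (liberal) accepts *within or
sister to*. The tool that popularized these statistics evaluates them
with regression curves fitted in earlier simulation studies; the
coefficients of those curves are not published in a reusable form, so
this package instead estimates the same definitions by direct
simulation of the query's attachment point:

1. draw a member $m \in M(g)$ uniformly;
2. draw a divergence $\delta$ as the patristic distance from $m$ to
   another uniformly chosen member (for singletons: to the nearest
   assigned non-member tip, the distance at which a query would start
   being confused with the neighbouring group);
3. attach the query lineage at height $h \sim U(0, \delta)$ on the
   path from $m$ towards the root;
4. score *within* if $h < d(m, \mathrm{MRCA}(g))$, *sister* if $h$
   lands on the MRCA's subtending branch, *misidentified* beyond it.

The estimate is the replicate mean; the 95% interval is a percentile
bootstrap (1000 resamples) of the replicate scores. The estimator is
seeded and bit-reproducible; `delimit_table()` derives one independent
stream per haplogroup from its single seed so that adding or removing
groups does not perturb the others. It reproduces the defining limits
(zero Intra with large Inter gives liberal ≈ 1; the mean is
non-increasing in Intra/Inter) but its numerical values for singleton
haplogroups will not match the fixed singleton output of the original
plugin, whose formula is unpublished. Replicate counts below 1000 are
allowed for exploration but warned about in the pipeline
configuration.

## Alignment distances

All pairwise counts use *pairwise deletion*: a site contributes to a
pair only when both sequences carry an unambiguous A/C/G/T. IUPAC
ambiguity codes are treated as missing rather than fractionally
matched, so counts are integers and reproducible. This matches the
default treatment for gappy degraded-DNA alignments; complete deletion
would discard most sites at ~11% missing data.

- $p$-distance: differing fraction of compared sites.
- K2P: $d = -\tfrac12\ln(1-2P-Q) - \tfrac14\ln(1-2Q)$ with transition
  and transversion proportions $P$, $Q$. Outside the logarithms'
  domain the pair is reported `NA` with a "saturated pair" warning —
  not clamped.
- GTR distance: with $F$ the symmetrized joint base-frequency matrix
  of the pair and $\Pi = \mathrm{diag}(\pi)$,
  $d = -\mathrm{tr}\,\Pi \log(\Pi^{-1} F)$, evaluated through the
  eigendecomposition of $\Pi^{-1/2} F \Pi^{-1/2}$ (similar, hence real
  spectrum); non-positive eigenvalues mean saturation (`NA` with
  warning). Base frequencies default to the pooled pair; bases absent
  from both sequences are dropped from the state space rather than
  treated as an error. No gamma correction is applied to K2P or GTR —
  the distances are the classical closed forms.

Grouped matrices average pairwise distances within and between
haplogroups; singleton groups have `NA` within-group entries, while
their between-group means are computed directly from the single
sequence (mathematically identical to the duplicate-the-sequence
workaround some tools require). Reports multiply by 100 and print one
decimal, the conventional percent layout (diagonal within-$p$, lower
triangle between-$p$, upper triangle K2P).

The saturation profile tabulates, per pair, the GTR-corrected distance
with transition and transversion proportions. Transition-biased,
unsaturated data shows $s > v$ throughout with both increasing in
distance; $v$ overtaking $s$ at high distance is the saturation
signature.

# The synthetic-data generator

The generator exists so that every estimator can be exercised against
known truth without any sequence downloads. It emulates the
statistical structure of a multi-species mitochondrial CYTB study; it
does not emulate alignment error, indels, codon structure,
heterogeneous sampling bias, or among-lineage rate variation, so a
green test establishes correct statistical behaviour of the
estimators, not robustness to real-data artifacts.

**Gene trees.** Species trees are ultrametric with branch lengths in
coalescent units (1 unit = 2N generations). Within each species-tree
branch, gene lineages coalesce at the Kingman rate (each pair at rate
$1/N_{rel}$); surviving lineages are pooled at species divergences and
coalesce to a single root above the species root. Branch lengths are
converted to expected substitutions/site by $\mu$, the substitution
rate per coalescent unit. Expected within-species pairwise divergence
is therefore $2\mu$ and between-species divergence
$2\mu(\tau + 1)$ for divergence time $\tau$; incomplete lineage
sorting appears naturally when $\tau$ is comparable to 1.

**Sequences.** Sites evolve independently under Kimura's two-parameter
model (transition:transversion *rate* ratio $\kappa$; equal base
frequencies), with optional gamma rate heterogeneity and a proportion
of invariant sites. Site rates are renormalized to mean 1 so branch
lengths stay calibrated in expected substitutions/site regardless of
$\alpha$ and $p_{inv}$. K2P(+Γ+I) rather than full GTR is a deliberate
choice: it exercises every estimator in the package (p, K2P, GTR
distance, saturation counts) while keeping closed-form expectations
available for tests; a full-GTR simulator would add parameters no test
can currently falsify. Missing data is injected by overwriting exactly
`round(fraction × cells)` uniformly chosen cells with `N`.

**Presets.** All preset parameters are fixed once, from the regime
they are meant to emulate, and are not tuning knobs:

- `deer-like`: 17 haplogroups with 1–20 tips each (three singletons,
  112 tips total), a coalescent-shaped species tree rescaled to root
  depth 6 coalescent units, $\mu = 0.01$/unit, $\kappa = 8$,
  $\Gamma(\alpha = 0.5)$ with 30% invariant sites, $L = 1140$ (the
  CYTB gene length), 11% missing data. This yields within-group
  p-distances of roughly 0–3% and between-group distances of roughly
  2–13%, the ranges typical of a dense mitochondrial sampling of
  closely related deer species.
- `deep`: 8 species, ladder divergences of 25–33 coalescent units.
  The parameter-recovery acceptance property presumes between:within
  divergence ≥ 10:1; because the within-species genealogy's depth has
  an exponential-tailed distribution, divergences of ~10 units make
  the *realized* ratio dip below 10:1 in a non-negligible fraction of
  groups, so the preset is placed deep enough that the premise holds
  with margin. The property thresholds themselves (monophyly,
  Intra/Inter < 0.15, liberal P ID > 0.9) are the stated ones.
- `shallow`: 8 species at 0.8–1.6 coalescent units, the incomplete
  lineage-sorting regime, used to verify that the pipeline surfaces
  non-monophyly rather than to assert clean recovery.

# Numerical and interface choices

- **Newick dialect**: support values as internal node labels, branch
  lengths after `:`; strict parsing rejects unbalanced parentheses,
  duplicate or empty tip labels, negative branch lengths, and missing
  branch lengths unless a documented zero default is enabled.
- **Rounding** (reports only; computation is full precision):
  distances 3 decimals, Av (MRCA–tips) 4, ratio and P ID 2, percent
  matrices 1 — the precisions of the conventional published layouts.
  `NA` is written literally, and each NA's cause is logged to stderr.
- **Determinism**: a single integer seed drives every stochastic
  stage; per-group and per-stage streams are derived from it, and the
  caller's RNG state is restored afterwards. Reports regenerate
  byte-identically under the same configuration.
- **Tie-breaks**: closest-haplogroup ties go to the lexicographically
  smallest name (warned); member sets are iterated in sorted order so
  results are invariant to input row order.
- **Degenerate inputs**: one-haplogroup assignments, empty alignments,
  zero-comparable-site pairs and saturated pairs fail or return `NA`
  loudly, never silently.

# Known limitations

- P ID values are definition-faithful but not numerically
  interchangeable with the fitted-curve implementation, most visibly
  for singleton haplogroups.
- The GTR distance is the classical matrix-logarithm estimator; it is
  not an ML distance under GTR+Γ+I with optimized parameters.
- The simulator draws one locus; it does not model recombination,
  migration, hybridization, or selection, and its clock is strict.
- Statistics are only as meaningful as the input branch lengths;
  consensus trees with non-substitution scales yield tree distances
  that should be compared only within that tree.
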