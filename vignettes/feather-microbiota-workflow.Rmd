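---
title: "Feather microbiota analysis: models, assumptions and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Feather microbiota analysis: models, assumptions and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# Scope

`featherbiome` implements a complete community-level analysis of avian
feather microbiota (FM) profiled by 16S rRNA amplicon OTU tables, together
with a synthetic-study generator that produces data with known ground truth
under the same design the analysis assumes. The workflow has five analytic
layers:

1. **Alpha diversity** — rarefaction to even depth, Shannon diversity
   (nats) and OTU richness, compared among host species by one-way ANOVA
   with `R2 = SS_between / SS_total`.
2. **Beta diversity** — Bray-Curtis, binary Jaccard, and unweighted and
   weighted UniFrac, with NMDS visual scaling, PERMANOVA, and Mantel tests
   against geographic distance.
3. **Spatially controlled host-species tests** — distance-based RDA on the
   positive-eigenvalue PCoA embedding of a dissimilarity matrix,
   constraining on host species and on spatial eigenfunctions (PCNM), with
   marginal Freedman-Lane permutation tests, forward selection, and
   adjusted-R² variance partitioning between host phylogeny and geography.
4. **Cophylogeny** — PACo-style Procrustean superimposition of the
   PCoA-scaled microbiota dissimilarity onto the PCoA-scaled host
   cophenetic distances, with a permutation test and pooling over a
   posterior sample of host trees.
5. **Functional fractions and their correlates** — identity-threshold
   best-hit mapping of OTU sequences against bacteriocin-producing (BPB,
   classes I-III) and keratinolytic feather-damaging (FDB) reference
   sequences, read-weighted and OTU-count proportions and overlaps, and a
   Bayesian phylogenetic mixed model relating those fractions to FM
   diversity with within/between-species centering.

# Models and conventions

## Rarefaction and diversity

Rarefaction draws once, without replacement, from each sample's read
multiset down to the common depth (default 2299 reads, the smallest depth
in the emulated design). A single draw (rather than an average over many)
is used; the seed is an explicit argument so results are reproducible.
Shannon diversity uses the natural log.

## Dissimilarities

Weighted UniFrac is reported **normalized** by default (divided by
`sum_b l_b (p_A(b) + p_B(b))`, bounding it in [0, 1] and making pairs
comparable); the raw variant is available with `normalized = FALSE`. The
bacterial tree is used as rooted and is never re-rooted; OTUs present in
the tree but absent from the table contribute no branch mass. Trees whose
branch lengths are all zero are rejected.

## Ordination and permutation tests

PCoA retains axes with eigenvalues above a relative tolerance of 1e-8 and
reports negative eigenvalues rather than correcting them (no
Cailliez/Lingoes step): db-RDA operates on the positive-eigenvalue axes
only. PERMANOVA uses free permutation of samples (no strata), matching the
plain analysis the workflow is built around. NMDS minimises Kruskal
stress-1 through `vegan::monoMDS`, from one metric (PCoA) start plus a
configurable number of random starts; the lowest-stress solution is kept,
so adding restarts can never worsen the result. Permutation p-values are
always `(1 + #{stat* >= stat}) / (1 + n_perm)`.

Marginal db-RDA tests use Freedman-Lane residual permutation: the response
is re-assembled from the reduced-model fit plus permuted reduced-model
residuals, and the marginal F is recomputed. Forward selection adds the
candidate with the smallest marginal p (ties broken towards the larger
adjusted-R² gain) and stops when the best p exceeds `alpha` or when the
selected set's adjusted R² would exceed that of the full candidate model.
The cap is deliberately not applied to the first admitted variable: with
noise candidates in the pool the full model's adjusted R² is diluted below
that of a single informative predictor, and the cap would otherwise veto
every selection.

PCNM spatial eigenfunctions truncate the geographic distance matrix at the
longest minimum-spanning-tree edge (overridable), replace larger entries
with four times the truncation distance, and keep the positive-eigenvalue
PCoA axes. Only the first three axes enter the Table-1-style db-RDA by
default, to limit model complexity; this is configurable. Great-circle
distances use the haversine formula with Earth radius 6371 km.

## PACo

Both distance matrices are PCoA-scaled and each configuration is
normalised to unit total sum of squares, so the Procrustes residual m² is
invariant to the overall scale of either matrix. The microbiota
configuration is fitted onto the host configuration (host phylogeny as the
independent reference). The null permutes whole samples (rows) of the
microbiota configuration, preserving its internal geometry — the "random
communities" null. Conspecific samples produce tied rows in the host
configuration; PCoA handles the ties naturally and no jitter is added.
Per-tree results over a posterior sample are pooled as mean m² and median
p, and the per-tree vectors are always returned.

## Identity-threshold functional mapping

OTU representatives are aligned to reference sequences semi-globally (free
terminal gaps; match +1, mismatch −1, gap open −5, gap extend −2);
identity is matches over alignment columns excluding terminal-gap columns,
with internal gaps counting as mismatches. Exhaustive best-hit comparison
replaces heuristic candidate ordering — at the scale of an OTU table this
is feasible and strictly more accurate, with identical acceptance
semantics (assigned iff identity ≥ threshold, default 0.97). One guard is
added: if the best-scoring overlap covers less than half of the shorter
sequence, the pair is scored as having no detectable similarity. Without
this, any two dissimilar sequences acquire near-perfect "identity" from a
degenerate few-base terminal overlap; production mappers impose the same
kind of coverage requirement. Both read-weighted and OTU-count
proportions are computed, since both conventions are in common use.

## The phylogenetic mixed model

The Gaussian model is `y = X beta + Z u + Z a + e` with iid species
effects `u ~ N(0, sigma2_s I)`, phylogenetically structured species
effects `a ~ N(0, sigma2_p A)` (A the unit-diagonal shared-branch-length
correlation from the host tree), and residuals `e`. The fixed design
decomposes each predictor into the species mean (between-species slope)
and the deviation from it (within-species slope), optionally with
species-specific within-slopes as the interaction model. Predictors that
are proportions are log-transformed first; zeros are offset by half the
smallest nonzero value.

The sampler is a conjugate Gibbs scheme: the full location block
(fixed + both random effects) is drawn jointly from its multivariate
normal conditional via a Cholesky solve, and the three variances from
inverse-gamma conditionals with IG(0.001, 0.001) defaults (per-component
overrides available, e.g. to floor a variance near zero). Defaults are
60,000 iterations, 10,000 burn-in, thinning 25; the validation batteries
use shorter chains (6,000/1,000/10), which the coverage results below show
to be sufficient at this data size. DIC is
`2 * mean(deviance) - deviance(at posterior means)`;
`H2 = sigma2_p / (sigma2_p + sigma2_s + sigma2_e)`. Posterior draws over a
posterior sample of host trees are pooled with equal weight and summaries
recomputed on the pooled sample.

**Identifiability caveat.** With seven host species, `u` and `a` are
nearly confounded: any species-level variance is split between them and
the H2 posterior stays diffuse. This mirrors the well-known behaviour of
species-level phylogenetic models on few species (broad credible
intervals). Consequently the "no phylogenetic signal ⇒ H2 near zero"
validation is run on data generated with *no species-level variance of
either kind*; when iid species variance is present, H2 is simply not
identified from seven species and no sampler could concentrate it.

# The synthetic-study generator

The generator emulates the sampling design the analysis assumes: 7 host
species, 72 samples (11, 11, 10, 10, 10, 10, 10), up to 9 localities in a
Czech-Republic-sized bounding box, minimum depth 2299 reads plus Poisson
over-dispersion, and trait fractions of 24.5% BPB / 12.2% FDB with 92% of
FDB also BPB. The species-to-locality design intentionally confounds some
species with single sites (three species each at one locality, one species
alone at the last three), so the db-RDA disentangling step is genuinely
exercised.

Mechanisms, chosen for being the simplest that generate each target
pattern:

- **Phylosymbiosis**: per-OTU species effects are Brownian motion on the
  host tree; the sd `phylosymbiosis_strength` is the single knob.
- **Spatial signal**: per-OTU locality effects from a Gaussian process
  with a squared-exponential kernel over great-circle distances
  (`spatial_range` default 100 km) — smooth clinal variation.
- **Counts**: sample log-intensities (baseline + species + locality +
  noise) map through a softmax to multinomial probabilities.
- **Host-tree posterior**: one Yule tree scaled to unit height; copies
  with lognormal branch-length jitter, rescaled, topology preserved.
- **Sequences**: Jukes-Cantor evolution along a Yule OTU tree (rate 0.1
  per unit height over 250 bp), so sequence divergence tracks patristic
  distance. Because real OTUs are 97%-identity clusters, representatives
  of distinct OTUs are never near-identical; the generator enforces a
  minimum pairwise divergence (default 5.5%, safely past both the 0.95
  and 0.97 mapping thresholds so that no OTU pair straddles them).
- **References**: copies of the designated OTU sequences (optionally
  mutated), plus random decoys far from every OTU.
- **Mixed-model data**: `y = alpha + beta_b * mean_s(x) + beta_w *
  (x - mean_s(x)) + u_s + a_s + e` with all parameters recorded; the
  default between-species slope (−4.5) echoes the magnitude of the
  interspecific diversity-BPB association the design emulates.

What the generator does **not** emulate: read-level error and chimeras,
compositional sequencing artefacts, variable 16S copy number, taxonomic
structure of the reference databases, and any real spatial habitat
structure. Passing validation on these data therefore demonstrates
correctness of the estimators under the generating model, not robustness
to every artefact of real amplicon data.

# Validation design and problem sizes

The test suite validates each layer against an independent route:

- UniFrac against a per-branch tip-classification oracle (50 random 8-tip
  instances, 1e-12) and against `phyloseq::UniFrac`; Ward merges against a
  brute-force ESS oracle; Procrustes m² against a rotation-angle grid
  search (1e-5); Mantel and PERMANOVA p-values against exhaustive
  enumeration at n = 4-5; PERMANOVA/Mantel statistics against vegan.
- Null calibration: PERMANOVA, Mantel, marginal db-RDA and PACo p-values
  over 500 null simulations each (199 permutations) are uniform (KS at
  alpha 0.01) with rejection at 0.05 inside [0.03, 0.07].
- Power: with `phylosymbiosis_strength = 2`, the species term of the
  db-RDA reaches p <= 0.005 (999 permutations) and PACo p < 0.05 in at
  least 19 of 20 seeds at the full 72-sample design.
- Estimator recovery: mutation-free references recover the designated
  trait sets exactly (pool of 250 OTUs); uniform-abundance read fractions
  match the designated fractions within multinomial error; the 0.97/0.95
  threshold concordance exceeds r = 0.8.
- Mixed model: the 95% credible interval covers the injected
  between-species slope (−4.5) in at least 90 of 100 replicates at 6,000
  iterations; H2 concentrates near zero without species-level variance;
  DIC prefers the interaction model in at least 8 of 10 seeds when
  species-specific slopes (±2) are injected.

`scripts/acceptance.R` reruns the full pipeline on one default-design
study (300 OTUs, 20 host trees, 999/499 permutations, 10 pooled chains of
6,000 iterations) and reports the headline quantities as JSON. These sizes
are the package's reporting defaults for a desk run; every one of them is
an argument.

# Known limitations

- Weighted UniFrac normalization conventions differ across software; the
  normalized variant here matches the common branch-mass normalization
  (and `phyloseq`), and the choice is recorded, not hidden.
- The dominant-OTU threshold for the heatmap (default 1% mean relative
  abundance within at least one species) is a configurable convention.
- Marginal db-RDA term variances do not sum to the constrained variance
  unless terms are orthogonal; they are model-comparison quantities.
- The phylogenetic mixed model is Gaussian-only, with species-level
  phylogenetic effects (7 levels in the emulated design): H2 is reported
  with its full posterior precisely because point estimates at this size
  are weakly informative.
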