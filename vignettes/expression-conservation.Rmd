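---
title: "Coexpression networks and the expression-conservation statistic"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coexpression networks and the expression-conservation statistic}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coexcons)
```

# Scope

`coexcons` implements a comparative-transcriptomics workflow around a gene
family of interest (the motivating case is the expansin cell-wall proteins
in ferns): build query-centred coexpression networks within each species,
pair "highly similar orthologs" between two species, and quantify how well
each ortholog pair's *coexpression context* — not its raw profile — is
conserved across species, using an iterative weighted-correlation
expression-conservation (EC) statistic. Because the tissue panels profiled
in two species rarely match in number or kind, profiles cannot be compared
column by column; the EC statistic works instead on each species' internal
gene–gene correlation structure, which is comparable even when the
condition sets are disjoint.

# The coexpression side

## Filtering

Starting from a genes × samples FPKM matrix, two filters are applied on the
raw scale before anything else:

* genes with mean FPKM < 0.1 are treated as non-expressed;
* genes with a coefficient of variation (CV = sd/mean, sample standard
  deviation with denominator $n-1$) < 0.5 are treated as constitutively
  expressed and uninformative for coexpression.

Removal uses strict inequality, so boundary values survive. Both filters
are computed on raw FPKM because the transformation comes next in the
procedure; the CV of a log-transformed row would be a different statistic.
Remaining values are mapped through $\log_2(x + 1)$. The pseudocount is a
deliberate choice: filtered matrices can still contain zero-FPKM cells, and
$-\infty$ must never reach a correlation. It also maps 0 to 0 and preserves
ordering, which is all a rank-based correlation sees.

Replicate handling is opt-in: `average_replicates()` collapses replicate
columns to condition means, but the default pipeline correlates the matrix
as supplied, since averaging is a modelling decision the user should make
explicitly.

## Edges, mutual rank, reliability

For each query gene, Spearman correlation against every other gene is
computed (rank transform with average ranks on ties, then Pearson on the
ranks). Edges are called when $|\rho| > 0.95$ and $p < 10^{-5}$ (both
strict), keeping the sign: strong negative coexpression is biologically
meaningful (e.g. repressed targets) and is retained as a negative edge.

The p-value uses the two-sided t approximation
$t = \rho\sqrt{(n-2)/(1-\rho^2)}$ on $n-2$ degrees of freedom, the standard
choice for Spearman at moderate $n$; $|\rho| = 1$ is reported as $p = 0$
and passes any threshold. An exact permutation option (full enumeration,
feasible for $n \le 9$) is available for small panels.

Correlation thresholds alone over-call edges, so each scored (query,
partner) pair is rescored by the mutual rank,
$\mathrm{MR}(ab) = \sqrt{\mathrm{Rank}(a \to b)\,\mathrm{Rank}(b \to a)}$,
where $\mathrm{Rank}(a \to b)$ is partner $b$'s position in $a$'s partner
list ordered by descending $|\rho|$ (rank 1 = strongest; fractional
average ranks on ties). Ranking by $|\rho|$ rather than signed $\rho$ keeps
strong negative partners highly ranked, consistent with retaining negative
edges. The ranking universe is *all* scored partners of a gene, not only
edge-passing ones, so MR reflects the full correlation context. An edge is
flagged *reliable* when its MR is among the smallest
$k = \lceil 0.01\,N \rceil$ over the $N$ scored pairs; ties at the cutoff
are all included, which makes the rule order-independent and reproducible.
The top fraction is computed globally over all query–partner pairs by
default (a per-query variant would change the meaning of the 1%).

# The orthology side

"Highly similar orthologs" between two species must satisfy two criteria
jointly: (1) reciprocal best BLASTP hits with e-value < $10^{-5}$ in *both*
directions, and (2) co-membership in one orthogroup. The e-value gate is
applied *before* best-hit selection, so a query whose best raw hit fails
the gate gets no ortholog rather than silently inheriting its second-best
hit. Ties are broken by bitscore, then lexicographically smallest subject
id — an arbitrary but deterministic rule. Multiple HSPs per (query,
subject) collapse to the minimal e-value / maximal bitscore row at load
time. The intersection of the two criteria matters: RBH alone admits
spurious one-off similarities, and orthogroups alone admit many-to-many
families; requiring both yields the one-to-one high-confidence pairs the
EC statistic assumes.

Gene-family candidates (for the expansin screen) are retained only when
they carry *every* required conserved domain — by default DPBB_1 and
Expansin_C, the two-domain architecture diagnostic of expansins. Domain
names are matched case-insensitively with `-` and `_` interchangeable,
since both conventions occur in annotation tools.

# The EC statistic

Given $n$ ortholog pairs with expression matrices
$E^{A}_{g,x}$ ($n$ genes × species-A conditions) and $E^{B}_{g,y}$, each
matrix is converted to its $n \times n$ Pearson correlation matrix $R^A$,
$R^B$, rows ordered identically by the pairing. The initial score is

$$\mathrm{EC}_0(i) = \mathrm{PCC}\!\left(R^A_{i,g},\, R^B_{i,g}\right),$$

the correlation between the two rows describing how pair $i$ correlates
with every other pair, computed over the $n-1$ off-diagonal positions. The
self entry is excluded: it is identically 1 in both matrices and would
inflate every score by a constant artifact.

Iteration then focuses the comparison on pairs that are themselves
conserved. At step $k$, every pair's score is recomputed as a weighted
Pearson correlation over the positions
$g' = \{\,l \ne i : \mathrm{EC}_{k-1}(l) > 0\,\}$, with weights
$w_l = \mathrm{EC}_{k-1}(l)$:

$$\mathrm{EC}_k(i) = \mathrm{PCC}_w\!\left(R^A_{i,g'},\, R^B_{i,g'}\right),
\qquad
\mathrm{PCC}_w(x, y) =
\frac{\sum w_l (x_l - \bar{x})(y_l - \bar{y})}
     {\sqrt{\sum w_l (x_l - \bar{x})^2}\,\sqrt{\sum w_l (y_l - \bar{y})^2}},$$

with weighted means $\bar x = \sum w_l x_l / \sum w_l$. Two details are
worth stating plainly:

* The denominator is the *symmetric* product of the two weighted
  root-sums-of-squares. This is the only form bounded in $[-1, 1]$;
  an asymmetric denominator would make the statistic unbounded.
  The weighted means are likewise required for invariance under positive
  affine transforms of either argument.
* Non-positive-EC pairs are excluded *as weights only*. Their own EC is
  still recomputed at every iteration, so a pair can re-enter the positive
  set later; nothing is frozen.

Iteration stops when $\sum_i [\mathrm{EC}_k(i) - \mathrm{EC}_{k-1}(i)]^2 <
0.1$ (the published stopping constant) or at a cap of 100 iterations, with
the convergence flag recording which occurred. The cap is a guard the
original description does not need in practice — the loose tolerance makes
convergence fast — but an implementation must terminate. Pairs whose EC is
undefined (a degenerate, zero-variance correlation row) are dropped with a
warning before iteration rather than silently zero-weighted; if fewer than
3 positively weighted pairs remain at any step, the run aborts with a
"weight support collapsed" error rather than returning meaningless scores.

EC is computed per ordered species pair with species A as the reference,
but the statistic is symmetric in its two inputs (asserted in the test
suite via simultaneous row/column permutations).

Downstream summaries mirror common practice: EC distributions of two gene
sets are compared with the two-sided Mann–Whitney U test (normal
approximation with tie correction), and a focal subset is placed against
the genome-wide distribution by the fraction of its values at or above the
empirical 95th percentile (nearest-rank quantile).

# The synthetic-data generator

No real RNA-seq is shipped or required: generators produce every input with
known ground truth, seeded and bit-reproducible as pure functions of
(config, seed).

## Single-species matrices (`simulate_expression`)

A latent-factor model on the log2 scale: each module has a standard-normal
activity per condition; a gene's signal is
`baseline + loading × activity(module, condition) + noise`, replicate
columns sharing the condition activity with independent noise, and
FPKM recovered as $2^{\text{signal}} - 1$ floored at 0. A `flat_fraction`
of genes carries no loading, exercising the CV filter, and a fraction of
loadings is negative (repressed module members), producing genuine negative
edges. Genes here have single module membership: the tight within-module
correlation this produces is exactly what the stringent $|\rho| > 0.95$
edge rule needs for planted positives to exist at all.

Defaults mirror a scaled-down version of the motivating study design:
5 conditions × 2 biological replicates, 200 genes, 4 modules, baseline
$\log_2$ FPKM of 3, loading 2, noise sd 0.25 (log2 units).

## Two-species ortholog pairs (`simulate_species_pair`)

Condition panels are drawn *independently* per species — deliberately not
matched, because coping with non-matching tissue panels is the reason EC
exists. Here each gene's program is a *mixture*: a primary module plus a
secondary module with weight drawn from $U(0.2, 0.8)$ (unit-variance
scaled) and a loading sign. The mixture matters: with single memberships,
a correlation row takes essentially one value per module — on the order of
"number of modules" effective degrees of freedom — and no statistic could
rank pairs reliably from it. Mixtures spread true inter-gene correlations
over a continuum, giving rows gene-level texture; negative loadings extend
that continuum over $[-1, 1]$.

A `conserved_fraction` of pairs inherits the complete program (primary,
secondary, weight, sign) in species B. Each remaining pair is driven by a
*private* latent program mixed with a random shared module, emulating
diverged, gene-specific regulation. Private programs keep the planted
labels identifiable: if diverged pairs were instead reassigned among the
shared modules, two of them landing in the same (A-module, B-module) cell
would genuinely share a conserved neighbourhood — their truth label would
say "diverged" while their expression said otherwise — and the iteration
would amplify such accidental consensus.

## Orthology tables (`simulate_orthology_tables`)

True pairs receive mutual hits with e-values log-uniform in
$[10^{-50}, 10^{-10}]$. Decoys are either gate-failing hits
($[10^{-4}, 10^{-2}]$) or passing but sub-best one-directional hits
($[10^{-9}, 10^{-6}]$), so recovery must genuinely use the gate and
reciprocity; additional decoy gene pairs form reciprocal best hits *across
different orthogroups*, so the orthogroup constraint is load-bearing too.
A domain table plants the two expansin domains on a candidate subset with
some candidates missing the second domain.

## What the generator does not emulate

Passing recovery tests on these data shows the algorithms behave as
specified under a linear latent-factor world with Gaussian log-scale noise.
Real RNA-seq additionally has counting noise scaling with expression,
batch effects, unbalanced library sizes, many-to-many orthology, and
correlation structure far richer than a handful of programs. Results here
are claims about the *methods*, not reproductions of any species-level EC
values, which depend on the real accessions and are out of scope.

# Numerical choices

* Correlations within $10^{-12}$ of $\pm 1$ are snapped to exactly
  $\pm 1$, so collinear inputs (e.g. identical matrices supplied as both
  species) hit the exact fixed point EC ≡ 1 with a zero convergence delta.
* Ranking ties always take fractional average ranks — deterministic and
  order-independent.
* The top-1% MR cutoff uses $k = \lceil 0.01 N \rceil$ with cutoff ties
  included.
* Best-hit ties break by bitscore then subject id; every tabular output is
  written in a deterministic order, and pipeline outputs embed the tool
  version, a config hash and the seed, making reruns byte-identical.
* Zero-variance profiles are excluded from correlation scoring (partners)
  or raise errors naming the offending genes (EC input), never silently
  imputed.

# Problem sizes

The test-suite and acceptance-script simulations run at deliberately modest
scale, chosen as the smallest sizes at which the statistical claims are
stable: networks on 80–200 genes with 10–20 samples; EC on 100 ortholog
pairs × 10 conditions per species (20 seeds for recovery, 100 for null
calibration); orthology on 40–50 pairs × 20 seeds. The implementation
itself is vectorised over the correlation matrices and handles
genome-scale inputs (thousands of genes) without modification.

# Known limitations

* The Spearman p-value's t approximation is inaccurate below ~5 samples;
  use the exact option there.
* MR computation scores each partner's full correlation row, so the
  all-pairs table grows quadratically in gene count; for very large
  genomes, restrict the matrix to expressed, variable genes first (the
  filter stage does this naturally).
* With non-positive EC support below 3 pairs the iteration aborts by
  design; extremely diverged species pairs can hit this, and the right
  reading is "EC is not estimable here", not a numeric failure.
* One-to-one pairing discards paralog fan-outs; genes without a qualifying
  partner are simply absent from the EC analysis.
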