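---
title: "Methods: mitogenome diversity, haplotype networks and symmetry-aware skull morphometrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mitogenome diversity, haplotype networks and symmetry-aware skull morphometrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(norppa)
```

This vignette is the package's own account of the methods it implements:
the models and their assumptions, the tunable parameters and why their
defaults are what they are, what the synthetic-data generator does and
does not emulate, and the numerical and design choices made where the
underlying publications leave details open.

## The scientific setting

Ringed seals occur across the Arctic, with landlocked relict populations
in Lake Saimaa and Lake Ladoga and a brackish-water population in the
Baltic Sea. Two independent data types carry the signal of their
divergence: mitogenome haplotypes (maternal, non-recombining) and skull
shape (polygenic, environment-sensitive). The pipeline quantifies, for
each sampling area, how much variation there is, how strongly areas are
differentiated, and whether the differentiation crosses the thresholds
proposed for subspecies and species delimitation — net nucleotide
divergence $d_A > 0.0006$ (subspecies) and $d_A > 0.008$ (species) for
mitogenomes, and percent diagnosability $> 80\%$ for morphology.

## Mitogenome statistics

### Missing data: complete deletion

All diversity statistics drop every alignment column that contains `N` or
a gap in any sequence of the analysed subset before anything is counted.
This makes the identity $\pi \cdot L_{\text{compared}} = K$ exact (it is
asserted to $10^{-12}$ in the tests), makes haplotype membership
unambiguous, and matches the default behaviour of the standard
DNA-polymorphism software. The number of compared sites is recorded in
every output. Pairwise deletion would retain more sites per pair at the
cost of breaking that identity; it is deliberately not offered.

### Diversity

For a subset of $n$ sequences: segregating sites $S$ count compared
columns with at least two bases; haplotype diversity uses the unbiased
estimator $H_d = \frac{n}{n-1}(1 - \sum_i p_i^2)$; $K$ is the mean of all
$\binom{n}{2}$ Hamming distances and $\pi = K / L_{\text{compared}}$,
reported both per site and on the $\times 100$ scale on which mitogenome
tables conventionally print it.

The probability $P$ of observing exactly $h$ haplotypes under the neutral
infinite-alleles model is the Ewens sampling formula
$P(h \mid n, \theta) = |s(n,h)|\,\theta^h / \prod_{i=0}^{n-1}(\theta+i)$,
with unsigned Stirling numbers of the first kind evaluated through their
triangular recurrence in log space (stable to $n$ in the hundreds; the
probabilities sum to one to $10^{-9}$ for $n \le 50$ in the tests). The
publications that print this column do not name their $\theta$ estimator;
this package uses Watterson's $\theta_W = S / \sum_{i<n} 1/i$ from the
same subset, on the per-locus scale, and treats close agreement rather
than digit-exact reproduction of $P$ as the attainable goal.

### Differentiation

$K_{ST} = 1 - K_S/K_T$, where $K_T$ is the mean pairwise difference in
the pooled two-population sample and $K_S$ the weighted mean of the
within-population values. The default weights are proportional to the
number of pairs $n_j(n_j-1)/2$ (the pair-count weighting of Hudson, Boos
and Kaplan); sample-size weights $n_j/n$ are available via
`weighting = "size"`. Significance comes from permuting population labels
with group sizes fixed, 1000 permutations by default, and the p-value
uses the $(1+b)/(N+1)$ convention so it can never be exactly zero. The
seed is mandatory and logged in the result. On tiny samples the
Monte-Carlo p agrees with exhaustive enumeration of all label splits (the
test suite checks $n = 4$ and $n = 8$ exhaustively).

$d_A = d_{XY} - (d_X + d_Y)/2$ uses uncorrected p-distances — consistent
with the count-based statistics elsewhere in the pipeline; no
substitution-model correction is applied anywhere.

Two finite-sample facts are worth knowing, because they contradict naive
expectations: for two literally identical population multisets, $K_{ST}$
and $d_A$ are slightly *negative*, not zero, because within-population
means exclude self-pairs while the pooled/between means include identical
cross-pairs. The expectations over random assignment of a pool to two
labels are exactly zero, and that is what the tests assert.

### Median-joining network

The construction follows Bandelt, Forster and Röhl. A link $(u,v)$ at
distance $d$ is feasible when $u$ and $v$ are not connected by links
strictly shorter than $d - \varepsilon$ (equivalently
$d \le \text{minimax}(u,v) + \varepsilon$, computed by the min-max closure
of the distance matrix); at $\varepsilon = 0$ this is the union of all
minimum spanning trees. For every mutually linked triple the quasi-median
is formed position-wise (majority state; positions with three distinct
states contribute all three resolutions); medians within $\varepsilon$ of
the pass's minimal connection cost are added, the network is rebuilt, and
passes repeat until stable (hard cap `max_iter = 50`, an error rather
than silent truncation). Finally, inferred nodes of degree $\le 2$ whose
removal leaves the observed haplotypes connected at unchanged total cost
are pruned. The published software's exact obsolete-node criterion is not
printed anywhere; small topological differences around median nodes
relative to published figures are expected and acceptable. Node identity
uses the variable columns only, and processing order is lexicographic, so
the output is byte-stable. The three-haplotype star (`AAT`, `ATA`, `TAA`)
is the canonical correctness check: one inferred median (`AAA`), three
weight-1 edges, Steiner cost 3 against an MST cost of 4.

## Skull geometric morphometrics

### Superimposition with object symmetry

Centroid size is $\mathrm{CS} = \sqrt{\sum_k \lVert x_k - \bar{x}
\rVert^2}$ (mm). Generalized Procrustes analysis centres each
configuration, scales it to unit centroid size and iteratively rotates it
to the consensus until the consensus moves less than $10^{-8}$ in
Procrustes distance (maximum 100 iterations; non-convergence is an
error). Rotations are proper ($\det = +1$): reflection is handled
exclusively by the symmetry machinery, never by the fitting.

Because the vertebrate skull is bilaterally symmetric, each configuration
and its mirrored, relabelled copy (x-axis negated, left/right landmark
indices swapped) are superimposed jointly, and the specimen's *symmetric
component* — the average of its two aligned copies — feeds all downstream
analyses. This removes both the redundancy of paired landmarks and the
asymmetric variation. The convention here averages the two aligned copies
after the joint superimposition; whether the reference software averages
before or after a final alignment pass is not documented to the last
digit, which is why reproduction of published distance tables is expected
at roughly two significant figures rather than exactly.

### Allometry, PCA, classification

Size-related shape variation is removed by one pooled multivariate
regression of all Procrustes coordinates on $\log_{10}\mathrm{CS}$;
downstream analyses use the residuals. Two caveats of this (standard)
design are documented rather than hidden: with finite samples the pooled
regression absorbs whatever group–size correlation exists by chance, so a
fraction of a true group difference of order
$r(\text{group}, \log \mathrm{CS}) \cdot \lVert \Delta \rVert$ leaks into
the residual scatter; and in the degenerate case where size is a pure
function of group the regression removes the group difference entirely.
The tests therefore isolate the classifier from the regression where the
property under test concerns classification alone.

PCA is on the covariance matrix of the residuals, with the sign of each
component fixed so its largest-magnitude loading is positive. All
multivariate comparisons use the first 10 PCs (configurable), following
the published choice made to keep the variable count below the smallest
group sizes. Truncating inside a noise-degenerate block of eigenvalues
makes PC-subspace statistics sensitive to tiny perturbations; that is a
property of truncation, not of the implementation, and the invariance
tests are run in regimes with a clear eigen-gap.

Classification is the strict Lachenbruch jackknife: for every held-out
specimen, group means *and* the pooled within-group covariance are
re-estimated from the remaining specimens, and the specimen is assigned
to the group with minimal Mahalanobis distance, equal priors, ties broken
by declared group order. The same machinery restricted to two groups
gives the pairwise percent diagnosability. Its assignments agree with an
independent linear-discriminant implementation with leave-one-out
cross-validation on well-separated data (checked in the tests).
Hotelling's $T^2$ uses the pooled two-sample covariance with the standard
$F$ transformation, $F = T^2 (n_A+n_B-p-1) / (p(n_A+n_B-2))$.

Sexual dimorphism uses only known-sex specimens. Discriminant vectors
$S^{-1}(\bar{x}_A - \bar{x}_B)$ are computed in the 10-PC subspace — the
space in which they are estimable with these sample sizes; the
publications do not state the space they used, and full-space vectors
from the same machinery are available by passing more PCs. Angles are
$\arccos$ of the normalized dot product, in degrees. Dispersion within an
area is the Procrustes distance of each specimen to its group mean; both
dispersion and centroid size are compared between areas with Welch $t$
tests by default (`pooled_var = TRUE` restores the classical
equal-variance Student test; the source material says only "Student's
t-tests").

## The synthetic-data generator

The generator exists so that every stage has inputs with known truth.

*Haplotypes*: an ancestral random sequence; lineages on a chain separated
by fixed numbers of mutations at previously untouched sites; populations
drawing from lineages by mixture weights; per-sequence private mutations
(Poisson, again at fresh sites). Because mutated sites never collide,
expectations are exact: the net divergence between two pure-lineage
populations is (separating mutations)/$L$ regardless of the private
draws, private mutations give within-population $K = 2\lambda$ in
expectation, and a single lineage with no mutations gives $H_d = \pi = 0$.
It is *not* a coalescent: there is no genealogical variance within
lineages, no realistic base composition and no mutation spectrum, so
passing tests demonstrate correctness of the statistics, not realism of
the data. A structured-coalescent generator would be the natural
extension.

*Landmarks*: a deterministic bilaterally symmetric template (12 pairs + 7
midline points by default, skull-like proportions in mm), unit centroid
size; per-group mean offsets, a sex-dimorphism vector and an allometric
slope, all drawn (or supplied explicitly) in the centred symmetric
subspace so they survive the symmetry machinery; isotropic Gaussian
landmark noise; scaling to a log-normal centroid size and a random
rotation + translation per specimen to mimic arbitrary digitizer frames.
Digitizing error in real data is neither isotropic nor homogeneous across
landmarks, and real group differences are not random directions; the
generator validates machinery, not biology.

One geometric subtlety matters when checking recovery of the allometric
field: superimposition estimates shape effects only within the tangent
space (translation, scale and the three infinitesimal rotations are
projected out — 7 of $3k$ dimensions), so recovered vectors are compared
against the truth *projected into that space*; comparing against the raw
truth vector shows a spurious ~25° angle that is pure geometry.

## Problem sizes and determinism

The test suite and the acceptance script run on deliberately small
problems: toy alignments of 4–10 sequences for oracle and exhaustive-
permutation checks, a four-area alignment of 62 sequences × 2000 bp and a
five-group landmark set of 100 specimens × 31 landmarks for the
end-to-end runs, and 100 seeded replicates of 11-landmark datasets for
parameter-recovery statistics — sizes chosen so the whole suite completes
in well under a minute while every code path is exercised. All randomness
flows from explicit seeds; rerunning any driver or the acceptance script
with the same seed reproduces every output byte for byte, and written
tables carry the seed and a configuration hash in a header comment.

## Known limitations

- The data-reproduction acceptance tests require the study's supplementary
  alignment and landmark files, which are not redistributable with the
  package; they fail visibly (not skip) when the files are absent.
- Reproduction of published morphometric tables is expected to ~2
  significant figures, because the reference software's symmetric-
  component and regression conventions are not published to the digit.
- $d_A$ and $K_{ST}$ are finite-sample estimators with the small negative
  bias described above; the taxonomic thresholds are applied to the point
  estimates, as in the source material, without propagating that bias.
- The pooled allometric regression can absorb true group differences when
  size is confounded with group; a pooled *within-group* regression would
  avoid this but would no longer match the published procedure.
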