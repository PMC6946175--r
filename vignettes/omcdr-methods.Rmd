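---
title: "Overlap matrix completion for drug repositioning: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Overlap matrix completion for drug repositioning: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(omcdr)
```

## The problem

Drug repositioning asks which already-approved drugs might treat which
diseases. The data are a heterogeneous network: an $m \times m$ drug–drug
similarity matrix $A_{RR}$ (e.g. from chemical fingerprints), an
$n \times n$ disease–disease similarity $A_{DD}$ (e.g. from phenotype
text mining), and a sparse binary disease–drug association matrix
$A_{DR} \in \{0,1\}^{n \times m}$ in which 1 marks a validated indication
and 0 means *not yet validated* — crucially, not *known absent*. Optional
protein panels ($A_{PR}$, protein–drug; $A_{DP}$, disease–protein) add a
third layer of evidence. omcdr consumes these matrices as precomputed
delimited text files; computing similarities from raw structures or
ontologies is out of scope.

Under the assumption that the full indication matrix is approximately
low-rank — drugs act through a limited number of mechanism classes —
association prediction becomes matrix completion on *block* matrices that
overlap the association block with the similarity blocks, so that completed
entries are informed by both layers.

## Cold-start KNN preprocessing

A *novel* disease (drug) has an all-zero row (column) of $A_{DR}$, which
gives the completion nothing to work with. Before completion, each all-zero
row $p$ is replaced by a similarity-weighted average of the association
profiles of its $K$ nearest neighbours $U$ under $A_{DD}$:

$$A_{DR1}(p, \cdot) = \frac{\sum_{u \in U} A_{DD}(p,u)\, A_{DR}(u, \cdot)}
                            {\sum_{u \in U} A_{DD}(p,u)},$$

and symmetrically each all-zero column is filled from drug-similarity
neighbours to give $A_{DR2}$. Both fills start from the original $A_{DR}$
and are computed independently. Filled values are convex combinations of
binary profiles, hence lie in $[0,1]$; known entries are never overwritten,
and the operation is the identity when no cold node exists, so the pipeline
applies it unconditionally.

Three details the algorithm statement leaves open are resolved as follows.
The query node is never its own neighbour: with unit self-similarity it
would contribute a zero profile while inflating the normaliser, uniformly
shrinking the fill. Ties in similarity are broken by ascending index so
results are platform-independent. If all $K$ neighbour similarities are
exactly zero there is no information to borrow; the row stays zero and a
warning is emitted.

## Bounded nuclear-norm-regularized completion (BNNR)

Each assembled block matrix $M$ with observed-entry set $\Omega$ is
completed by solving

$$\min_X \; \|X\|_* + \frac{\alpha}{2}\,\|P_\Omega(X) - P_\Omega(M)\|_F^2
\quad \text{s.t.} \quad 0 \le X \le 1,$$

where $\|X\|_*$ is the nuclear norm (the convex surrogate for rank),
$P_\Omega$ zeroes unobserved entries, $\alpha > 0$ balances data fit
against rank, and the box constraint keeps every completed entry
interpretable as an association likelihood. The regularized (rather than
exact) fit term absorbs noise in the similarity entries.

The solver is ADMM on the splitting $X = W$ with penalty $\beta > 0$:

1. **W-update** (closed form): with
   $Z = Y/\beta + (\alpha/\beta) P_\Omega(M) + X$, the unconstrained
   minimiser is $W^* = (I - \frac{\alpha}{\alpha+\beta} P_\Omega)(Z)$ —
   entries on $\Omega$ are scaled by $\beta/(\alpha+\beta)$ — and the
   subproblem is separable and quadratic per entry, so clamping to $[0,1]$
   gives the exact box-constrained solution.
2. **X-update**: singular value thresholding
   $X \leftarrow D_{1/\beta}(W - Y/\beta)$, the proximal operator of the
   nuclear norm (each singular value shrunk by $1/\beta$, those at or below
   it dropped).
3. **Dual ascent**: $Y \leftarrow Y + \beta (X - W)$.

Initialisation is $X = W = Y = P_\Omega(M)$; the completed matrix returned
is the final $W$, whose entries are exactly within $[0,1]$ because the last
operation applied to it is the clamp.

**Stopping rule.** The iteration stops when the relative primal residual
$\|X - W\|_F / \max(1, \|X\|_F)$ falls below `tol` ($10^{-4}$ by default)
*and* the relative change between successive $X$ iterates falls below
$10 \times$ `tol`. The second condition matters: early in the run $X$
tracks $W$ closely long before either is near the optimum, and on larger
problems the primal residual alone can dip below $10^{-4}$ within two
iterations while the completion is still essentially the initial projection.
The successive-change condition is the cheap analogue of the ADMM dual
residual and rejects that transient; requiring it to reach `tol` itself
would multiply the iteration count roughly eightfold for no measurable gain
in prediction quality, so the looser factor of 10 is used. `max_iter`
defaults to 300; hitting it sets a non-convergence flag that is carried
into the prediction's provenance and raised as a warning, never silently
ignored.

**Which entries are observed.** The composition of $\Omega$ for a block
matrix is the single most consequential convention in the method, and two
modes are provided:

* `blockwise` (default): similarity blocks are fully observed — a zero
  similarity is a measured dissimilarity, not missing data — while zeros in
  the association and protein blocks are unobserved candidates. Entries
  made nonzero by the KNN fill count as observed; that is their purpose.
* `nonzero`: only nonzero entries anywhere are observed, for users whose
  similarity matrices use 0 to encode "not computed".

Protein–drug and disease–protein panels are binary association data of the
same character as $A_{DR}$, so under `blockwise` their zeros are likewise
treated as unobserved.

## The OMC2 and OMC3 pipelines

OMC2 (bilayer) assembles the drug-side matrix
$M_1 = \begin{bmatrix} A_{RR} \\ A_{DR1} \end{bmatrix} \in
\mathbb{R}^{(m+n) \times m}$ and the disease-side matrix
$M_2 = [\,A_{DR2}, A_{DD}\,] \in \mathbb{R}^{n \times (m+n)}$, completes
each with BNNR, extracts the two predicted association blocks (the last $n$
rows of $M_1^*$; the first $m$ columns of $M_2^*$), and returns their
unweighted entrywise mean. OMC3 (tri-layer) inserts the protein panels
between the similarity and association blocks,
$M_1 = [A_{RR}; A_{PR}; A_{DR1}]$ and $M_2 = [A_{DR2}, A_{DP}, A_{DD}]$;
with empty panels the assembled matrices are identical and OMC3 reproduces
OMC2 exactly. The one-sided ablations (OMC-drug, OMC-disease) return a
single side's block without averaging, so their mean equals the OMC2 output
by construction. Block positions are carried in an explicit layout object
and extraction always reads from it, never from recomputed shapes. The
completed similarity and protein blocks are retained in the returned fit
objects for inspection but take no further part, and the non-square block
matrices are completed as-is — no symmetrisation happens inside the solver.

Solver inputs are deterministic functions of the dataset, so predictions are
reproducible bit-for-bit and invariant (to numerical precision) under
relabelling of drugs, diseases, or proteins.

**Defaults** $\alpha = 1$, $\beta = 10$, $K = 10$ are the grid-search
optima reported for the standard gold-standard benchmark of this method
family; the grid itself ($\alpha, \beta \in \{0.1, 1, 10, 100\}$,
$K \in \{1, 5, 10, 15, 20, 25, 30\}$) is available via the CLI `tune`
subcommand.

## Evaluation protocols

**Repeated cross-validation.** Known associations (1-entries) are
partitioned per repeat into 10 folds of near-equal size (default
10 repeats). Each fold in turn is zeroed in the training matrix — which
also removes those entries from $\Omega$ — the predictor is refit, and for
every test drug all diseases except that drug's *remaining training
positives* are scored as candidates. Held-out positives are ranked among
candidates with midranks under ties (the unbiased convention for AUC).
ROC/PR curves and AUC/AUPR are computed on the candidate scores pooled
within each repeat and averaged across repeats; a per-drug macro-averaged
AUC is available as an option, since pooling versus macro-averaging is a
genuine protocol choice and the two can differ when score scales vary
across drugs. Top-$k$ counts report how many held-out associations rank
within the top $k$ candidates of their drug, $k \in \{1,5,10,30,50,100\}$;
"within" is rank $\le k$.

**De novo test.** Drugs with exactly one known association are eligible; in
turn, that association is removed — leaving an all-zero column that
exercises the cold-start KNN path — the model is refit, and the removed
disease's rank among all diseases is recorded. AUC is computed on the
scores pooled over eligible drugs.

Leakage is structurally impossible in both protocols: the predictor sees
only the zeroed training matrix, and the test indices are asserted absent
from the solver's observed set by the test suite.

## The synthetic generator

Offline validation uses planted-truth datasets that emulate the *structure*
of real drug-repositioning benchmarks: a sparse binary association matrix
with low-rank latent structure, bounded noisy similarities with unit
diagonal, and designated cold-start nodes. Nonnegative latent factors
$F_d \in \mathbb{R}^{m \times r}$, $F_s \in \mathbb{R}^{n \times r}$
(absolute-valued Gaussians, so inner products are naturally nonnegative)
define a propensity matrix $F_s F_d^\top$; the top `density` fraction of
entries (exact count, by quantile thresholding — deterministic fixture
sizes) become associations. Similarities are the cosine similarities of the
factors plus symmetric truncated Gaussian noise (`noise`, default 0.1),
clamped to $[0,1]$ with the diagonal restored to 1. Cold drugs/diseases
have their association column/row zeroed, with the removed links recorded
as ground truth; optional "single-association" drugs keep only their
strongest indication, providing eligible cases for de novo experiments.
Protein panels are generated from the *same* latent factors, so protein
evidence genuinely carries the association signal — in particular for cold
drugs, whose protein interactions survive the zeroing.

Default sizes are $m = 120$ drugs, $n = 80$ diseases, rank $r = 5$,
density 0.08, and 6 cold drugs + 4 cold diseases (about 5% of each axis, so
the cold-start path is exercised by default). These sizes make a full
10-fold CV of OMC2 run in seconds while leaving hundreds of held-out
associations per fold plan.

Two benchmark constructions deserve explanation:

* **Planted rank-2 recovery.** With i.i.d. positive factors a rank-2
  product is spectrally dominated by its first singular value
  ($\sigma_2/\sigma_1 \approx 0.1$), and since the $\alpha = 1$
  regularization imposes a fixed absolute shrinkage (about
  $(1 + \beta/\alpha)/\beta \cdot$ a constant) on each singular value, the
  weak second component is largely destroyed no matter how accurately the
  solver converges. The recovery fixture therefore plants a
  *balanced-spectrum* rank-2 matrix — two factor pairs loading on
  complementary halves of the rows and columns
  ($\sigma_1 \approx 24$, $\sigma_2 \approx 11$ at $150 \times 100$) — at a
  size where both singular values dominate the shrinkage bias. Under that
  construction, half the entries observed suffice for a relative error
  below 0.1 on the unobserved half.
* **Tri-layer de novo benchmark.** At the default noise level the
  similarities alone already place the removed indication of a cold drug
  near the top (AUC ≈ 0.997), leaving protein evidence no room to help. The
  tri-layer benchmark therefore raises the similarity noise to 0.3 and uses
  $s = t = 100$ proteins, so the cold-start signal must flow through the
  protein panels; there OMC3 matches or exceeds OMC2. Because both methods
  operate near ceiling, the comparison is made at a fixed seed; across
  arbitrary seeds inversions of a few thousandths occur.

What passing these tests does *not* show: real similarity matrices are not
noisy cosines of the factors that generated the associations — their
information content is far lower and their noise is structured; real
association matrices have heavy-tailed margins (blockbuster drugs, rare
diseases) rather than quantile-flat density; and protein panels are not
conditionally independent given latent factors. Absolute AUC values on
synthetic data are therefore optimistic and only *relative* behaviour
(identities, orderings, degradation under noise) should be read across to
real data.

## Numerical choices and degenerate inputs

* All accumulation is in double precision; the $[0,1]$ bound is enforced by
  clamping, so boundary values are exactly 0 or 1.
* The SVT step uses a full thin SVD of the dense iterate each iteration;
  block matrices in this problem class are at most a few thousand per side,
  where LAPACK's dense SVD is faster and more robust than truncated
  alternatives.
* Similarity matrices asymmetric by at most $10^{-8}$ are silently averaged
  with their transpose; larger asymmetry is an error, not a warning, since
  silently averaging genuinely asymmetric data would corrupt KNN
  neighbourhoods.
* Empty protein panels ($s = 0$ or $t = 0$) are first-class and reduce OMC3
  to OMC2 bitwise. Zero-height/width blocks never enter the assembled
  matrix.
* Matrix files are written with 17 significant digits, so write/read
  round-trips are exact for doubles.
* Neighbour ties, candidate-ranking ties, and score ties in metrics are all
  resolved deterministically (ascending index, lexicographic identifier,
  midrank respectively).

## Known limitations

* The de novo protocol refits the full model once per eligible drug;
  for hundreds of eligible drugs on large networks this is the dominant
  cost (it is exact, not approximated).
* $\Omega$'s composition on real datasets depends on whether exact-zero
  off-diagonal similarities mean "measured zero" or "not computed"; the
  package cannot infer this and exposes both conventions (`omega_mode`).
* The square symmetric heterogeneous completion used by some baseline
  methods (a single matrix containing all blocks including
  protein–protein) is intentionally not implemented.
* Weighted averaging of the two side predictions is out of scope; the mean
  is unweighted by design.
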