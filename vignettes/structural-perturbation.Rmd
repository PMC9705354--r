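---
title: "Structural perturbation matrix completion: model, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structural perturbation matrix completion: model, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spmc)
```

## The model

`spmc` predicts unobserved links in a bipartite interaction network — the
motivating case is lncRNA–miRNA interactions, where only a few thousand
pairs are experimentally confirmed. The working hypothesis is the standard
one for molecular interaction prediction: functionally similar RNAs tend to
share interaction partners. The package therefore fuses three sources into
one symmetric bilayer adjacency matrix over the N = m + n RNAs,

$$A = \begin{pmatrix} SL & LM \\ LM^{\top} & SM \end{pmatrix},$$

with $LM \in \{0,1\}^{m \times n}$ the known interactions and $SL$, $SM$
similarity networks in $[0,1]$ with unit diagonal.

Link scores come from first-order eigenvalue perturbation. A random subset
of $A$'s weighted edges is removed as a perturbation set (matrix $A_p$);
the retained network $A_r = A - A_p$ is diagonalised,
$A_r = \sum_k \lambda_k x_k x_k^{\top}$, and the removed edges are treated
as a perturbation that shifts each eigenvalue but not its eigenvector:

$$\Delta\lambda_k = x_k^{\top} A_p\, x_k, \qquad
\tilde A = \sum_k (\lambda_k + \Delta\lambda_k)\, x_k x_k^{\top}.$$

If the network's structure is regular enough, $\tilde A$ concentrates
weight on pairs that "belong" in the network — including pairs never
observed. Entries of $\tilde A$ in the $LM$ block rank candidate
interactions; entries in the similarity blocks are never ranked, since
predictions are interactions, not similarities. The final score matrix
averages $t$ independent draws of the perturbation set to reduce
selection bias.

Degenerate eigenvalues need care: when $\lambda$ is repeated with
multiplicity $M$, the eigenvector basis is defined only up to rotation, and
$x_k^{\top} A_p x_k$ depends on the arbitrary basis the solver returned.
The package then forms the $M \times M$ projection
$H_{qj} = x_q^{\top} A_p x_j$, solves $H B = \Delta\tilde\lambda B$, and
uses $H$'s eigenvalues as the corrections with the rotated basis
$\tilde x = \sum_j \beta_j x_j$. For $M = 1$ this reduces exactly to the
simple formula, and the test suite checks both branches against exact
diagonalisation.

Two identities make the method easy to validate and are enforced in tests:
the trace is conserved exactly
($\operatorname{tr}\tilde A = \operatorname{tr}A_r + \operatorname{tr}A_p$,
because the eigenvector basis is complete), and a perturbation that
commutes with $A_r$ (e.g. $A_p = cA_r$, or any $A_p$ when $A_r = I$) is
reproduced without first-order error. For generic perturbations the
spectrum of $\tilde A$ differs from the exact spectrum of $A_r + A_p$ at
second order: scaling $A_p$ by $\varepsilon$ shrinks the spectral error as
$O(\varepsilon^2)$, which the acceptance suite verifies by halving
$\varepsilon$ and observing the error quarter.

## Structural consistency

The same perturbation gives a model-free index of *link predictability*.
After perturbing, all node pairs outside the retained edge set — the
removed edges together with all never-observed pairs — are ranked by
$\tilde A$, and

$$\delta = \frac{|E^l \cap E_p|}{l}$$

is the fraction of the $l$ removed edges recovered in the top $l$ of that
ranking. A five-edge worked example fixes the convention: with removed
edges (1,6), (2,7), (2,9), (3,8), (4,12) and top-5 ranked pairs (1,6),
(2,9), (4,7), (4,8), (4,12), three of five removed edges are recovered and
$\delta = 0.6$. Note the ranked list may contain pairs that were never
edges at all — the candidate pool is everything outside $E_r$.
`structural_consistency()` reports mean ± sd over repeated draws, and
`consistency_ablation()` compares the four related networks ($LM$,
$LM+SM$, $LM+SL$, bilayer) by zeroing the omitted blocks.

## Similarity construction

* **Expression similarity** is the absolute Pearson correlation between
  expression profiles (vectors of $h \ge 2$ attributes). The absolute
  value is deliberate — the formula takes the magnitude of the covariance —
  so strongly anti-correlated profiles score as similar; the measure is
  invariant to affine rescaling of any profile. Pairs where a profile is
  missing or constant are *undefined*, not zero.
* **Sequence similarity** is a Needleman–Wunsch global alignment score.
  No standard parameterisation maps alignment scores into $[0,1]$, so the
  package uses edit-style scoring — match $+1$, mismatch $-1$, linear gap
  $-1$, all configurable — divides by the longer sequence length and clips
  negatives to zero. Identical sequences score exactly 1; U is normalised
  to T, case is folded, and ambiguous bases (N) never match, not even each
  other.
* **Integration** is the unweighted mean of the two similarities. Where
  the expression similarity is undefined the sequence similarity is used
  unchanged (and vice versa): averaging an undefined value as zero would
  halve the similarity of every RNA lacking expression data, whereas the
  point of carrying two similarity types is to complement missing
  information. Every similarity matrix has its diagonal forced to exactly
  1 and is validated (symmetric within 1e-12, entries in $[0,1]$).

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `t` | 16 | perturbations averaged per fit; the variance of the score matrix falls roughly as $1/t$, with diminishing returns near 16 |
| `fraction` | 0.1 | share of pool edges removed per draw (dimensionless); large enough to carry signal, small enough that first order holds |
| `pool` | `"all"` | which edges are perturbable (see below) |
| `k` | 5 | cross-validation folds |
| `neg_ratio` | 1 | sampled negatives per held-out positive |
| `repeats` | 20 | draws behind a consistency report |
| match/mismatch/gap | +1/−1/−1 | alignment scoring, exposed in `sequence_similarity()` and the CLI |

**The perturbation pool.** The bilayer graph is weighted: similarity
entries and interaction links are all edges. For structural consistency the
pool is necessarily all edges — the index perturbs the network as a whole.
For prediction the package also defaults to the all-edges pool, a
deliberate design choice: when only interaction links are perturbed, the
eigenvalue corrections $x_k^{\top} A_p x_k$ carry no information from the
similarity layers, and in our experiments on generated data the fused
network then predicts held-out links *worse* than the interaction network
alone — the fusion is wasted. Perturbing similarity and interaction edges
alike lets the corrections express all three information sources, restores
the expected ordering (bilayer above interaction-only), and matches the
view of the training object as one weighted graph whose edges include the
similarity weights. `pool = "interaction"` remains available.

## Evaluation protocol

Known interactions are shuffled into k folds (remainder spread one per
fold). Per fold, the test positives are zeroed in the training copy of
$LM$ — the test suite checks the fold's training bilayer contains no test
link — the model is fitted on the training bilayer, and held-out positives
are scored against sampled negatives. Two conventions deserve a note, since
interaction data contain no verified non-interactions:

* **Negatives** are unobserved pairs sampled uniformly without replacement,
  one per test positive by default. Unobserved pairs may contain true
  interactions, which biases absolute AUC slightly downward; this is the
  standard compromise in interaction prediction.
* **Threshold** for the confusion-matrix metrics is the median of the
  evaluated pair scores — a balanced decision point, chosen because no
  principled cutoff exists for dimensionless link weights. AUC is computed
  as the Mann–Whitney rank statistic (ties count one half) and is
  threshold-free; an independent ROC package cross-checks it in the tests.
* A metric whose denominator is zero (e.g. precision with no predicted
  positives) is reported `NA`, never silently 0.

## The synthetic generator

`simulate_lmi()` provides ground truth for testing without any external
database. It emulates exactly the structural assumption the method relies
on: nonnegative factors $U$ ($m \times r$), $V$ ($n \times r$) generate
both the interaction probabilities ($P \propto UV^{\top}$, scaled to a
target density, sampled entrywise Bernoulli) and the similarity layers
(cosine similarity of factor rows, so self-similarity is exactly 1, plus
symmetric Gaussian noise clipped to $[0,1]$). Defaults — $m = 60$,
$n = 30$, $r = 3$, density 0.08, noise sd 0.05 — keep an
eigendecomposition in the milliseconds and a full cross-validation in
seconds, the scale at which the whole test suite (including twenty-seed
ablation comparisons) runs in well under a minute.

What the generator does *not* emulate: real sequence or expression content
(similarities are planted directly, so the similarity-construction code is
tested separately on real formulas and oracles), hub-dominated degree
distributions, database biases, or the order-of-magnitude larger networks
of curated interaction databases. Passing the ablation tests on this data
shows the machinery extracts planted low-rank structure; it does not
certify performance numbers on any real database.

## Numerical choices

* Eigenvalues are grouped as degenerate when they differ by at most
  $10^{-8}\max(1, \lVert A_r \rVert_2)$; floating-point spectra are never
  exactly equal, and exact analysis only distinguishes equal vs unequal.
* Eigenvectors come from LAPACK's symmetric solver and are orthonormal;
  the correction formula's denominator $x_k^{\top}x_k$ is therefore 1.
* $\tilde A$ is symmetrised ($(\tilde A + \tilde A^{\top})/2$) to remove
  accumulation error; splits satisfy $A_r + A_p = A$ bit-exactly by
  construction (entries are moved, never recomputed).
* Ranking ties are broken by node-pair lexicographic order so every
  ranking is reproducible; ties have measure zero in floating scores.
* Sub-seeds for the $t$ draws (and for folds and negative sampling) are
  derived from the master seed via a seeded `sample.int`, recorded in the
  fitted object, and keep every derived seed a valid 32-bit integer.
* The diagonal (self-similarity 1) is never perturbable: self-loops are
  not links.
* Scores are ranked raw; negative entries of $\tilde A$ are not clipped,
  since only the order matters.

## Limitations

* First order only: corrections are linear in $A_p$; for large removed
  fractions the eigenvector-freezing assumption degrades. The
  $O(\varepsilon^2)$ guarantee is about the spectrum, not the
  eigenvectors.
* Dense algebra: $O(N^3)$ per perturbation. Fine for the intended scale
  ($N$ in the hundreds to low thousands); not engineered for sparse giant
  graphs.
* Absolute-correlation similarity treats anti-correlated expression
  profiles as similar by design; users who want signed similarity should
  supply their own matrix.
* Evaluation metrics beyond AUC depend on the negative-sampling and
  threshold conventions above and are not comparable across different
  conventions.
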