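# spmc — structural perturbation matrix completion for bipartite interaction networks

Experimentally confirmed lncRNA–miRNA interactions are scarce, and assaying
them is slow and expensive, so computational ranking of candidate pairs is a
standard first step before bench validation. `spmc` predicts missing links
in a bipartite molecular interaction network by treating link prediction as
matrix completion on a **bilayer network**: the known interactions plus two
node-similarity networks, fused into one symmetric adjacency matrix

```
A = | SL   LM  |        SL: m x m lncRNA similarity
    | LM'  SM  |        SM: n x n miRNA similarity
                        LM: m x n binary interaction matrix
```

The completion engine is **first-order structural perturbation**. A random
fraction of A's weighted edges is removed as a perturbation set `E_p`
(matrix `A_p`), the retained network `A_r = A − A_p` is diagonalised,
`A_r = Σ_k λ_k x_k x_k'`, and each eigenvalue is corrected by how strongly
the removed edges project on its eigenvector while the eigenvectors are kept
fixed:

```
Δλ_k = x_k' A_p x_k            (simple eigenvalues)
Ã    = Σ_k (λ_k + Δλ_k) x_k x_k'
```

For repeated eigenvalues the correction is obtained by diagonalising the
perturbation inside the degenerate subspace (`H_qj = x_q' A_p x_j`,
`H B = Δλ̃ B`), which rotates the basis before the same reconstruction.
Entries of `Ã` in the `LM` block score unobserved lncRNA–miRNA pairs; the
final score matrix averages `t` independent perturbations (default
`t = 16`, fraction 10%). The same machinery yields the **structural
consistency index** δ — the fraction of removed edges recovered in the top-l
of the perturbed ranking — a model-free measure of how predictable a
network's links are.

Similarities are built from expression profiles (absolute Pearson
correlation) and nucleotide sequences (normalised Needleman–Wunsch global
alignment), averaged pairwise with a fallback to the sequence similarity
where a profile is missing.

## Worked example

```r
library(spmc)

sim <- simulate_lmi(seed = 42)                 # planted 60 x 30 network
fit <- spmc(sim$lm, sim$sl, sim$sm, t = 16, seed = 1)
fit
#> Structural perturbation matrix completion fit
#>   network: 60 lncRNAs x 30 miRNAs (145 known interactions)
#>   perturbations averaged: t = 16  fraction = 0.1  pool = all
#>   master seed: 1

head(predict(fit), 5)                          # top novel candidates
#>   lnc_id  mi_id     score known
#> 1 lnc040 mir001 0.1915901 FALSE
#> 2 lnc058 mir030 0.1869184 FALSE
#> 3 lnc042 mir011 0.1855369 FALSE
#> 4 lnc012 mir021 0.1689540 FALSE
#> 5 lnc054 mir010 0.1646457 FALSE
```

Scores are entries of the averaged perturbed matrix: dimensionless link
weights, comparable within one fit, higher = more likely to interact.
Known training pairs are excluded from the ranking.

```r
net <- build_bilayer(sim$lm, sim$sl, sim$sm)
structural_consistency(net, repeats = 20, seed = 2)
#> Structural consistency: 0.9119 +/- 0.0159 (20 repeats, 10% of edges removed)

consistency_ablation(sim$lm, sim$sl, sim$sm, repeats = 10, seed = 4)
#>   network      mean         sd
#> 1      lm 0.1571429 0.06563833
#> 2   lm+sm 0.7517241 0.03271322
#> 3   lm+sl 0.9093750 0.01207814
#> 4 bilayer 0.8991489 0.01501805
```

δ ≈ 0.91 for the bilayer versus 0.16 for the bare interaction network: the
similarity layers make the planted links far more predictable, mirroring the
ordering they produce in held-out prediction accuracy:

```r
cross_validate(sim$lm, sim$sl, sim$sm, k = 5, t = 16, seed = 3)
#> 5-fold cross-validation (t = 16, fraction = 0.1)
#>   fold    AUC    FPR    TPR    Spe    Pre    Sen    Acc     F1
#> 1    1 0.7372 0.3103 0.6897 0.6897 0.6897 0.6897 0.6897 0.6897
#> ...
#> mean AUC 0.6021 +/- 0.1079
```

Held-out positives are scored against an equal number of sampled
never-observed pairs; AUC is threshold-free, the other metrics use a median
score cutoff.

A command-line front end wrapping these functions (subcommands `simulate`,
`similarity`, `build`, `predict`, `consistency`, `evaluate`, `rank`) is
installed at `system.file("cli/spmc-cli.R", package = "spmc")`.

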