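# Independent oracles and small generators shared across tests.

# Needleman-Wunsch global alignment score by direct dynamic programming,
# written independently of the package's alignment route.
nw_score_oracle <- function(a, b, match = 1, mismatch = -1, gap = -1) {
  a <- strsplit(a, "")[[1]]
  b <- strsplit(b, "")[[1]]
  na <- length(a); nb <- length(b)
  D <- matrix(0, na + 1, nb + 1)
  D[, 1] <- gap * (0:na)
  D[1, ] <- gap * (0:nb)
  for (i in seq_len(na)) {
    for (j in seq_len(nb)) {
      sub <- if (a[i] == b[j] && a[i] != "N") match else mismatch
      D[i + 1, j + 1] <- max(D[i, j] + sub, D[i, j + 1] + gap, D[i + 1, j] + gap)
    }
  }
  D[na + 1, nb + 1]
}

rand_sym <- function(n, scale = 1) {
  x <- matrix(rnorm(n * n, sd = scale), n)
  (x + t(x)) / 2
}

rand_seq <- function(len) paste(sample(c("A", "C", "G", "T"), len, TRUE),
                                collapse = "")

# minimal split object accepted by perturb_once()
raw_split <- function(A_r, A_p) list(A_r = A_r, A_p = A_p)

# bilayer with zero similarity blocks around a given binary LM matrix
lm_only_bilayer <- function(adj) {
  build_bilayer(interaction_network(adj))
}

# direct-formula confusion metrics, coded independently of compute_metrics;
# a ratio with zero denominator is undefined (NA), as is F1 when
# precision + sensitivity is zero or undefined
metrics_oracle <- function(tp, tn, fp, fn) {
  frac <- function(num, den) if (den > 0) num / den else NA_real_
  pre <- frac(tp, tp + fp)
  sen <- frac(tp, tp + fn)
  f1 <- if (is.na(pre) || is.na(sen) || pre + sen == 0) NA_real_ else
    2 * pre * sen / (pre + sen)
  c(FPR = frac(fp, tn + fp), TPR = sen, Spe = frac(tn, tn + fp),
    Pre = pre, Sen = sen, Acc = frac(tp + tn, tp + tn + fp + fn), F1 = f1)
}
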