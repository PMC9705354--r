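#' Simulate a planted low-rank interaction network
#'
#' Generates a synthetic lncRNA-miRNA dataset with the statistical structure
#' the predictor assumes: interactions arise from a low-rank nonnegative
#' factor model (functionally similar RNAs share interaction partners), and
#' the similarity networks reflect the same factors plus symmetric noise.
#' Nonnegative factors U (m x r) and V (n x r) are drawn, the interaction
#' probability matrix P is their scaled product mapped into [0, 1] at the
#' target density, the binary network is sampled entrywise Bernoulli(P), and
#' the similarity layers are the cosine similarities of the factor rows with
#' added symmetric Gaussian noise, clipped to [0, 1] with unit diagonal.
#'
#' @param m,n numbers of lncRNAs and miRNAs.
#' @param rank number of planted factors, at most \code{min(m, n)}.
#' @param density target expected interaction density in (0, 1).
#' @param noise standard deviation of the symmetric noise added to the
#'   similarity layers.
#' @param seed integer seed; the whole dataset is a deterministic function
#'   of it.
#' @return Object of class \code{"lmi_sim"}: list with the probability
#'   matrix \code{P}, the sampled \code{lm}
#'   (\code{\link{interaction_network}}), similarity matrices \code{sl} and
#'   \code{sm}, and the planted factors \code{U}, \code{V}.
#' @examples
#' sim <- simulate_lmi(seed = 42)
#' sim$lm
#' mean(sim$lm$lm)   # close to the target density
#' @export
simulate_lmi <- function(m = 60, n = 30, rank = 3, density = 0.08,
                         noise = 0.05, seed = NULL) {
  if (rank > min(m, n)) stop("rank must be <= min(m, n)")
  if (!(density > 0 && density < 1)) stop("density must be in (0, 1)")
  if (noise < 0) stop("noise must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  lnc_ids <- sprintf("lnc%03d", seq_len(m))
  mi_ids <- sprintf("mir%03d", seq_len(n))
  U <- matrix(abs(stats::rnorm(m * rank)), m, rank)
  V <- matrix(abs(stats::rnorm(n * rank)), n, rank)
  P0 <- U %*% t(V)
  P <- P0 * (density / mean(P0))
  if (mean(P > 1) > 0.01)
    stop("infeasible density for the drawn factors; lower density or rank")
  P <- pmin(P, 1)
  dimnames(P) <- list(lnc_ids, mi_ids)
  adj <- matrix(stats::rbinom(m * n, 1, P), m, n)
  lm <- interaction_network(adj, lnc_ids, mi_ids)
  sl <- factor_similarity(U, lnc_ids, noise)
  sm <- factor_similarity(V, mi_ids, noise)
  structure(list(P = P, lm = lm, sl = sl, sm = sm, U = U, V = V,
                 density = density, noise = noise, seed = seed),
            class = "lmi_sim")
}

# cosine similarity of factor rows (self-similarity exactly 1) plus
# symmetric Gaussian noise, clipped to [0, 1]
factor_similarity <- function(Fm, ids, noise) {
  nrm <- sqrt(rowSums(Fm^2))
  S <- (Fm %*% t(Fm)) / outer(nrm, nrm)
  if (noise > 0) {
    E <- matrix(stats::rnorm(nrow(Fm)^2, sd = noise), nrow(Fm))
    S <- S + (E + t(E)) / 2
  }
  S <- pmin(pmax(S, 0), 1)
  S <- (S + t(S)) / 2
  diag(S) <- 1
  dimnames(S) <- list(ids, ids)
  validate_similarity(S)
  S
}

#' @export
print.lmi_sim <- function(x, ...) {
  cat("Synthetic planted interaction dataset:", x$lm$m, "x", x$lm$n,
      "| realized density", round(mean(x$lm$lm), 4),
      "| similarity noise sd", x$noise, "\n")
  invisible(x)
}
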