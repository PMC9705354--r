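#' Fraction of removed edges recovered by a ranking
#'
#' The set-overlap at the heart of the structural consistency index: given
#' the top-l ranked node pairs after perturbation and the l removed edges,
#' returns |top ranked  removed| / l.  Pairs are unordered.
#'
#' @param top_edges two-column matrix or data.frame of the highest-ranked
#'   node pairs.
#' @param removed_edges two-column matrix or data.frame of the perturbation
#'   set E_p (l = its row count).
#' @return Proportion in [0, 1].
#' @examples
#' ep  <- rbind(c(1, 6), c(2, 7), c(2, 9), c(3, 8), c(4, 12))
#' top <- rbind(c(1, 6), c(2, 9), c(4, 7), c(4, 8), c(4, 12))
#' edge_recovery(top, ep)   # 3/5
#' @export
edge_recovery <- function(top_edges, removed_edges) {
  canon <- function(e) {
    e <- as.matrix(e)
    if (ncol(e) != 2) stop("edge sets must have two columns")
    paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]), sep = "\r")
  }
  removed <- canon(removed_edges)
  l <- length(removed)
  if (l == 0) stop("perturbation set is empty")
  length(intersect(canon(top_edges), removed)) / l
}

# rank all node pairs not in E_r by perturbed score and return the top-l;
# tie-break: score descending, then node-pair lexicographic
top_ranked_pairs <- function(At, split, l) {
  N <- nrow(At)
  cand <- which(upper.tri(At), arr.ind = TRUE)
  dimnames(cand) <- NULL
  retained <- matrix(FALSE, N, N)
  retained[split$E_r] <- TRUE
  retained[split$E_r[, 2:1, drop = FALSE]] <- TRUE  # orientation-free lookup
  keep <- !retained[cand]
  cand <- cand[keep, , drop = FALSE]
  sc <- At[cand]
  ord <- order(-sc, cand[, 1], cand[, 2])
  cand[ord[seq_len(min(l, nrow(cand)))], , drop = FALSE]
}

#' Structural consistency of a network (single draw)
#'
#' Removes a random fraction of the weighted edges, perturbs the remainder
#' (\code{\link{perturb_once}}), ranks every node pair outside the retained
#' set (removed and never-observed pairs alike) by perturbed score, and
#' reports the fraction of the removed edges recovered in the top l, where l
#' is the perturbation-set size.  A high value means the perturbation barely
#' changes the network's eigenstructure — the network's links are
#' predictable from its own structure, with no model assumptions.
#'
#' @param net a \code{"bilayer"} object.
#' @param fraction fraction of edges removed.
#' @param seed integer seed for the edge draw.
#' @return A single proportion in [0, 1].
#' @export
structural_consistency_once <- function(net, fraction = 0.1, seed = NULL) {
  split <- sample_perturbation_split(net, fraction, seed = seed, pool = "all")
  At <- perturb_once(split)
  l <- nrow(split$E_p)
  edge_recovery(top_ranked_pairs(At, split, l), split$E_p)
}

#' Structural consistency with repeated draws
#'
#' Repeats \code{\link{structural_consistency_once}} over independent,
#' seed-derived perturbation sets and reports mean and sample standard
#' deviation.
#'
#' @inheritParams structural_consistency_once
#' @param repeats number of independent draws.
#' @param seed master seed; per-draw seeds are derived from it.
#' @return Object of class \code{"consistency_report"}: list with
#'   \code{delta} (per-draw values), \code{mean}, \code{sd} (0 when
#'   \code{repeats == 1}), \code{fraction}, \code{repeats}, \code{seed}.
#' @export
structural_consistency <- function(net, fraction = 0.1, repeats = 20,
                                   seed = NULL) {
  if (repeats < 1) stop("repeats must be >= 1")
  seeds <- derive_seeds(seed, repeats)
  delta <- vapply(seeds, function(s)
    structural_consistency_once(net, fraction, seed = s), numeric(1))
  structure(
    list(delta = delta, mean = mean(delta),
         sd = if (repeats > 1) stats::sd(delta) else 0,
         fraction = fraction, repeats = repeats, seed = seed),
    class = "consistency_report")
}

#' @export
print.consistency_report <- function(x, ...) {
  cat(sprintf(
    "Structural consistency: %.4f +/- %.4f (%d repeats, %.0f%% of edges removed)\n",
    x$mean, x$sd, x$repeats, 100 * x$fraction))
  invisible(x)
}

#' Consistency of the four related networks
#'
#' Ablation comparison of link predictability: structural consistency of the
#' interaction network alone, with each similarity layer, and of the full
#' bilayer network, all on the same repeated perturbation protocol.
#'
#' @param lm an \code{\link{interaction_network}}.
#' @param sl,sm similarity matrices (see \code{\link{build_bilayer}}).
#' @inheritParams structural_consistency
#' @return data.frame with one row per network (\code{lm}, \code{lm+sm},
#'   \code{lm+sl}, \code{bilayer}) and columns \code{mean}, \code{sd}.
#' @export
consistency_ablation <- function(lm, sl = NULL, sm = NULL, fraction = 0.1,
                                 repeats = 20, seed = NULL) {
  full <- build_bilayer(lm, sl, sm)
  nets <- c("lm", "lm+sm", "lm+sl", "bilayer")
  res <- lapply(nets, function(w) {
    rep <- structural_consistency(ablate_bilayer(full, w), fraction,
                                  repeats, seed)
    data.frame(network = w, mean = rep$mean, sd = rep$sd,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
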