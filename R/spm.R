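#' Eigendecomposition with degeneracy grouping
#'
#' Diagonalises a symmetric matrix and partitions the spectrum into
#' degeneracy groups: runs of eigenvalues equal within
#' \code{tol_factor * max(1, ||a||_2)}.  Repeated eigenvalues leave the
#' eigenvector basis defined only up to rotation inside the group, which the
#' perturbation step must resolve.
#'
#' @param a symmetric numeric matrix.
#' @param tol_factor relative tolerance for grouping eigenvalues.
#' @return List with \code{values} (ascending), \code{vectors} (orthonormal
#'   columns, matching order) and \code{groups} (list of index vectors
#'   partitioning the spectrum).
#' @export
eigen_system <- function(a, tol_factor = 1e-8) {
  if (!is.matrix(a) || nrow(a) != ncol(a) || max(abs(a - t(a))) > 1e-10)
    stop("input must be a symmetric square matrix")
  es <- eigen(a, symmetric = TRUE)
  ord <- rev(seq_along(es$values))   # eigen() returns descending
  values <- es$values[ord]
  vectors <- es$vectors[, ord, drop = FALSE]
  tol <- tol_factor * max(1, max(abs(values)))
  gid <- cumsum(c(1L, diff(values) > tol))
  groups <- unname(split(seq_along(values), gid))
  list(values = values, vectors = vectors, groups = groups)
}

#' First-order structural perturbation of a network
#'
#' Given a split \code{A = A_r + A_p}, diagonalises the retained matrix
#' \code{A_r = sum_k lambda_k x_k x_k'} and estimates how the perturbation
#' set shifts each eigenvalue while keeping the eigenvectors fixed:
#' \code{delta_k = x_k' A_p x_k} for simple eigenvalues.  Inside each
#' degenerate group the basis is first rotated by diagonalising the group
#' projection \code{H}, \code{H_qj = x_q' A_p x_j}, whose eigenvalues are the
#' corrections and whose eigenvectors give the adapted basis.  The perturbed
#' matrix \code{sum_k (lambda_k + delta_k) x_k x_k'} is a linear
#' approximation of the full network whose entries score unobserved links.
#'
#' @param split a \code{\link{sample_perturbation_split}} result, or a list
#'   with symmetric matrices \code{A_r} and \code{A_p}.
#' @param tol_factor degeneracy grouping tolerance, see
#'   \code{\link{eigen_system}}.
#' @return The perturbed N x N matrix (symmetric; dimnames preserved).
#' @export
perturb_once <- function(split, tol_factor = 1e-8) {
  A_r <- split$A_r
  A_p <- split$A_p
  stopifnot(is.matrix(A_r), is.matrix(A_p), all(dim(A_r) == dim(A_p)))
  es <- eigen_system(A_r, tol_factor)
  lam <- es$values
  X <- es$vectors
  dlam <- numeric(length(lam))
  for (g in es$groups) {
    Xg <- X[, g, drop = FALSE]
    H <- crossprod(Xg, A_p %*% Xg)
    if (length(g) == 1L) {
      dlam[g] <- H[1, 1]
    } else {
      H <- (H + t(H)) / 2
      eh <- eigen(H, symmetric = TRUE)
      dlam[g] <- eh$values
      X[, g] <- Xg %*% eh$vectors
    }
  }
  At <- X %*% ((lam + dlam) * t(X))
  At <- (At + t(At)) / 2
  dimnames(At) <- dimnames(A_r)
  At
}

# deterministic sub-seeds for the t independent perturbations
derive_seeds <- function(master_seed, t) {
  if (is.null(master_seed)) return(rep(list(NULL), t))
  set.seed(master_seed)
  as.list(sample.int(.Machine$integer.max, t))
}

#' Structural perturbation matrix completion
#'
#' Fits the link predictor: builds the bilayer network from the known
#' interactions and the similarity layers, draws \code{t} independent
#' perturbation splits, computes the first-order perturbed matrix for each
#' (see \code{\link{perturb_once}}) and averages them.  Entries of the
#' averaged matrix in the lncRNA-miRNA off-diagonal block score candidate
#' interactions; higher means more likely to interact.  Similarity blocks are
#' never ranked as candidates.
#'
#' @param lm an \code{\link{interaction_network}} (the training
#'   interactions).
#' @param sl,sm similarity matrices for the two node sets, or \code{NULL} to
#'   zero that layer (ablations).
#' @param t number of independent perturbations averaged; more repeats
#'   reduce the variance due to perturbation-set selection.
#' @param fraction fraction of pool edges removed per perturbation.
#' @param seed master seed; per-perturbation seeds are derived from it and
#'   recorded in the fit.
#' @param pool edge pool the perturbation set is drawn from.  The default
#'   \code{"all"} perturbs similarity and interaction edges alike, so the
#'   eigenvalue corrections carry information from every layer;
#'   \code{"interaction"} restricts removal to interaction links.
#' @return Object of class \code{"spmc"}: list with the score block
#'   \code{scores} (m x n, named), the full averaged matrix \code{A_tilde},
#'   the logical \code{known} training mask, the \code{network} used, the
#'   derived \code{sub_seeds} and the call parameters.
#' @examples
#' sim <- simulate_lmi(m = 20, n = 10, seed = 7)
#' fit <- spmc(sim$lm, sim$sl, sim$sm, t = 4, seed = 1)
#' fit
#' head(predict(fit), 3)
#' @export
spmc <- function(lm, sl = NULL, sm = NULL, t = 16, fraction = 0.1,
                 seed = NULL, pool = c("all", "interaction")) {
  pool <- match.arg(pool)
  net <- if (inherits(lm, "bilayer")) lm else build_bilayer(lm, sl, sm)
  spmc_fit(net, t = t, fraction = fraction, seed = seed, pool = pool,
           call = match.call())
}

spmc_fit <- function(net, t, fraction, seed, pool, call = NULL) {
  stopifnot(inherits(net, "bilayer"))
  if (t < 1) stop("t must be >= 1")
  seeds <- derive_seeds(seed, t)
  N <- net$m + net$n
  acc <- matrix(0, N, N)
  for (r in seq_len(t)) {
    split <- sample_perturbation_split(net, fraction, seed = seeds[[r]],
                                       pool = pool)
    acc <- acc + perturb_once(split)
  }
  At <- acc / t
  dimnames(At) <- list(net$node_ids, net$node_ids)
  scores <- At[seq_len(net$m), net$m + seq_len(net$n), drop = FALSE]
  known <- net$A[seq_len(net$m), net$m + seq_len(net$n), drop = FALSE] != 0
  structure(
    list(scores = scores, A_tilde = At, known = known, network = net,
         t = t, fraction = fraction, seed = seed, sub_seeds = seeds,
         pool = pool, call = call),
    class = "spmc")
}

#' @export
print.spmc <- function(x, ...) {
  cat("Structural perturbation matrix completion fit\n")
  cat("  network: ", x$network$m, " lncRNAs x ", x$network$n, " miRNAs (",
      sum(x$known), " known interactions)\n", sep = "")
  cat("  perturbations averaged: t =", x$t, " fraction =", x$fraction,
      " pool =", x$pool, "\n")
  if (!is.null(x$seed)) cat("  master seed:", x$seed, "\n")
  invisible(x)
}

#' @method summary spmc
#' @export
summary.spmc <- function(object, ...) {
  s <- object$scores
  k <- object$known
  out <- list(
    m = object$network$m, n = object$network$n, t = object$t,
    fraction = object$fraction, n_known = sum(k),
    score_known = summary(s[k]), score_candidate = summary(s[!k]))
  class(out) <- "summary.spmc"
  out
}

#' @export
print.summary.spmc <- function(x, ...) {
  cat("spmc fit over", x$m, "x", x$n, "pairs;", x$n_known,
      "training interactions; t =", x$t, "\n")
  cat("scores of known training pairs:\n"); print(x$score_known)
  cat("scores of candidate (unobserved) pairs:\n"); print(x$score_candidate)
  invisible(x)
}

#' Predicted interaction scores
#'
#' Returns candidate lncRNA-miRNA pairs ranked by their perturbed-matrix
#' score, descending, with deterministic tie-breaking by ids.  Known training
#' interactions are excluded by default since they are not predictions.
#'
#' @param object an \code{"spmc"} fit.
#' @param top_k number of pairs to return (default: all).
#' @param exclude_known drop pairs already in the training network.
#' @param ... unused.
#' @return data.frame with columns \code{lnc_id}, \code{mi_id}, \code{score},
#'   \code{known}.
#' @export
predict.spmc <- function(object, top_k = Inf, exclude_known = TRUE, ...) {
  s <- object$scores
  df <- data.frame(
    lnc_id = rep(rownames(s), times = ncol(s)),
    mi_id = rep(colnames(s), each = nrow(s)),
    score = as.vector(s),
    known = as.vector(object$known),
    stringsAsFactors = FALSE)
  if (exclude_known) df <- df[!df$known, , drop = FALSE]
  df <- df[order(-df$score, df$lnc_id, df$mi_id), , drop = FALSE]
  rownames(df) <- NULL
  utils::head(df, top_k)
}

#' Plot score distributions of a fit
#'
#' Score densities of known training pairs versus unobserved candidate
#' pairs; separation indicates the completed matrix recovers the training
#' structure.
#'
#' @param x an \code{"spmc"} fit.
#' @param ... passed to \code{\link[graphics]{plot}}.
#' @method plot spmc
#' @export
plot.spmc <- function(x, ...) {
  dk <- stats::density(x$scores[x$known])
  du <- stats::density(x$scores[!x$known])
  graphics::plot(dk, col = "firebrick", lwd = 2, xlab = "interaction score",
                 main = "Score distribution", xlim = range(dk$x, du$x),
                 ylim = range(0, dk$y, du$y), ...)
  graphics::lines(du, col = "steelblue", lwd = 2)
  graphics::legend("topright", c("known pairs", "candidate pairs"),
                   col = c("firebrick", "steelblue"), lwd = 2, bty = "n")
  invisible(x)
}

#' Rank candidate partners for one RNA
#'
#' Case-study style ranking: all candidate partners of a query lncRNA or
#' miRNA sorted by predicted score, descending (ties broken by id).  For a
#' genuine case study, remove the query's interactions with
#' \code{\link{drop_interactions}} before fitting, then rank with
#' \code{exclude_known = FALSE} so every candidate competes.
#'
#' @param object an \code{"spmc"} fit.
#' @param query RNA identifier present in the fit.
#' @param direction rank miRNA partners of a lncRNA query, or lncRNA
#'   partners of a miRNA query.
#' @param top_k number of candidates returned.
#' @param exclude_known drop candidates already linked to the query in
#'   training.
#' @return data.frame with columns \code{candidate}, \code{score},
#'   \code{known}, ordered by decreasing score.
#' @export
rank_candidates <- function(object, query,
                            direction = c("mirnas_for_lncrna",
                                          "lncrnas_for_mirna"),
                            top_k = 10, exclude_known = TRUE) {
  stopifnot(inherits(object, "spmc"))
  direction <- match.arg(direction)
  if (direction == "mirnas_for_lncrna") {
    if (!query %in% rownames(object$scores)) stop("unknown lncRNA id: ", query)
    sc <- object$scores[query, ]
    kn <- object$known[query, ]
  } else {
    if (!query %in% colnames(object$scores)) stop("unknown miRNA id: ", query)
    sc <- object$scores[, query]
    kn <- object$known[, query]
  }
  df <- data.frame(candidate = names(sc), score = unname(sc),
                   known = unname(kn), stringsAsFactors = FALSE)
  if (exclude_known) df <- df[!df$known, , drop = FALSE]
  df <- df[order(-df$score, df$candidate), , drop = FALSE]
  rownames(df) <- NULL
  utils::head(df, top_k)
}

#' Remove all interactions of one RNA
#'
#' Zeroes the interaction row (lncRNA) or column (miRNA) of the query so the
#' predictor must recover its partners from the network structure alone —
#' the setup used for case-study validation.
#'
#' @param lm an \code{\link{interaction_network}}.
#' @param query RNA id present in the network.
#' @return A new \code{"lmi_network"} with the query's links removed.
#' @export
drop_interactions <- function(lm, query) {
  stopifnot(inherits(lm, "lmi_network"))
  adj <- lm$lm
  if (query %in% lm$lnc_ids) {
    adj[query, ] <- 0
  } else if (query %in% lm$mi_ids) {
    adj[, query] <- 0
  } else stop("unknown RNA id: ", query)
  interaction_network(adj, lm$lnc_ids, lm$mi_ids)
}
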