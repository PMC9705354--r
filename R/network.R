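#' Construct a bipartite interaction network
#'
#' Wraps a binary lncRNA x miRNA adjacency matrix together with its id
#' registries.  Rows index lncRNAs, columns miRNAs; an entry of 1 records a
#' known interaction.
#'
#' @param adjacency numeric matrix with entries in \{0, 1\}.
#' @param lnc_ids,mi_ids character vectors of unique identifiers; default to
#'   the dimnames of \code{adjacency}.
#' @return An object of class \code{"lmi_network"}: a list with elements
#'   \code{lm} (the binary matrix, with dimnames), \code{lnc_ids},
#'   \code{mi_ids}, \code{m} and \code{n}.
#' @examples
#' lm <- matrix(c(1, 0, 0, 1, 1, 0), nrow = 2,
#'              dimnames = list(c("l1", "l2"), c("m1", "m2", "m3")))
#' net <- interaction_network(lm)
#' net$m; net$n
#' @export
interaction_network <- function(adjacency,
                                lnc_ids = rownames(adjacency),
                                mi_ids = colnames(adjacency)) {
  adjacency <- as.matrix(adjacency)
  if (is.null(lnc_ids)) lnc_ids <- paste0("lnc", seq_len(nrow(adjacency)))
  if (is.null(mi_ids))  mi_ids  <- paste0("mir", seq_len(ncol(adjacency)))
  if (anyDuplicated(lnc_ids)) stop("duplicated lncRNA ids")
  if (anyDuplicated(mi_ids))  stop("duplicated miRNA ids")
  if (length(lnc_ids) != nrow(adjacency) || length(mi_ids) != ncol(adjacency))
    stop("id registries do not match adjacency dimensions")
  if (!all(adjacency %in% c(0, 1)))
    stop("adjacency entries must be 0 or 1")
  storage.mode(adjacency) <- "double"
  dimnames(adjacency) <- list(lnc_ids, mi_ids)
  structure(
    list(lm = adjacency, lnc_ids = lnc_ids, mi_ids = mi_ids,
         m = nrow(adjacency), n = ncol(adjacency)),
    class = "lmi_network")
}

#' @export
print.lmi_network <- function(x, ...) {
  cat("Bipartite interaction network:", x$m, "lncRNAs x", x$n, "miRNAs,",
      sum(x$lm), "known interactions\n")
  invisible(x)
}

#' Assemble the bilayer adjacency matrix
#'
#' Builds the symmetric (m + n) x (m + n) block matrix
#' \deqn{A = \begin{bmatrix} SL & LM \\ LM^T & SM \end{bmatrix}}
#' from the lncRNA similarity network \code{sl}, the miRNA similarity network
#' \code{sm} and the interaction network \code{lm}.  Passing \code{NULL} for a
#' similarity block zeroes it, which is how the LM-only and single-similarity
#' ablations are formed.
#'
#' @param lm an \code{\link{interaction_network}} object.
#' @param sl,sm square symmetric similarity matrices in [0, 1] whose dimnames
#'   equal \code{lm$lnc_ids} resp. \code{lm$mi_ids} in the same order, or
#'   \code{NULL} for a zero block.
#' @return An object of class \code{"bilayer"}: list with the full matrix
#'   \code{A}, \code{node_ids} (lncRNA ids then miRNA ids), \code{lnc_ids},
#'   \code{mi_ids}, \code{m}, \code{n}.
#' @seealso \code{\link{ablate_bilayer}}, \code{\link{spmc}}
#' @export
build_bilayer <- function(lm, sl = NULL, sm = NULL) {
  stopifnot(inherits(lm, "lmi_network"))
  m <- lm$m; n <- lm$n
  if (is.null(sl)) {
    sl <- matrix(0, m, m, dimnames = list(lm$lnc_ids, lm$lnc_ids))
  } else {
    validate_similarity(sl)
    if (!identical(rownames(sl), lm$lnc_ids))
      stop("sl ids do not match lncRNA ids of the interaction network: ",
           paste(symdiff_ids(rownames(sl), lm$lnc_ids), collapse = ", "))
  }
  if (is.null(sm)) {
    sm <- matrix(0, n, n, dimnames = list(lm$mi_ids, lm$mi_ids))
  } else {
    validate_similarity(sm)
    if (!identical(rownames(sm), lm$mi_ids))
      stop("sm ids do not match miRNA ids of the interaction network: ",
           paste(symdiff_ids(rownames(sm), lm$mi_ids), collapse = ", "))
  }
  A <- rbind(cbind(sl, lm$lm), cbind(t(lm$lm), sm))
  node_ids <- c(lm$lnc_ids, lm$mi_ids)
  dimnames(A) <- list(node_ids, node_ids)
  structure(
    list(A = A, node_ids = node_ids, lnc_ids = lm$lnc_ids,
         mi_ids = lm$mi_ids, m = m, n = n),
    class = "bilayer")
}

#' @export
print.bilayer <- function(x, ...) {
  cat("Bilayer network: N =", x$m + x$n, "nodes (", x$m, "lncRNAs +", x$n,
      "miRNAs ),", sum(x$A[upper.tri(x$A)] != 0), "weighted edges\n")
  invisible(x)
}

#' Zero out blocks of a bilayer network
#'
#' Convenience for the ablation comparison across the four related networks:
#' interaction-only (\code{"lm"}), interaction plus one similarity layer
#' (\code{"lm+sl"}, \code{"lm+sm"}) and the full bilayer.
#'
#' @param net a \code{"bilayer"} object.
#' @param network which blocks to keep.
#' @return A \code{"bilayer"} object with the omitted blocks set to zero.
#' @export
ablate_bilayer <- function(net,
                           network = c("bilayer", "lm", "lm+sl", "lm+sm")) {
  stopifnot(inherits(net, "bilayer"))
  network <- match.arg(network)
  m <- net$m; n <- net$n
  A <- net$A
  li <- seq_len(m); mi <- m + seq_len(n)
  if (network %in% c("lm", "lm+sm")) A[li, li] <- 0
  if (network %in% c("lm", "lm+sl")) A[mi, mi] <- 0
  out <- net
  out$A <- A
  out
}

# unordered edge pool of a bilayer network: 2-column integer matrix of node
# index pairs i < j with A[i, j] != 0; diagonal never included
edge_pool <- function(net, pool = c("all", "interaction")) {
  pool <- match.arg(pool)
  A <- net$A
  if (pool == "all") {
    idx <- which(upper.tri(A) & A != 0, arr.ind = TRUE)
  } else {
    m <- net$m
    lmblk <- net$A[seq_len(m), m + seq_len(net$n), drop = FALSE]
    idx <- which(lmblk != 0, arr.ind = TRUE)
    idx[, 2] <- idx[, 2] + m
  }
  dimnames(idx) <- NULL
  idx
}

#' Split a bilayer network into retained and perturbation edge sets
#'
#' Randomly removes a fraction of the weighted edges of the bilayer graph to
#' form a perturbation set E_p, leaving the retained set E_r, realised as
#' symmetric matrices with \code{A_r + A_p = A} exactly.  Self-similarity
#' diagonal entries are never sampled.
#'
#' @param net a \code{"bilayer"} object.
#' @param fraction proportion of pool edges moved to the perturbation set,
#'   in (0, 1); the set size is \code{round(fraction * pool size)}.
#' @param seed integer seed making the draw reproducible.
#' @param pool \code{"all"} draws from every nonzero off-diagonal entry
#'   (similarity and interaction weights alike, as used for structural
#'   consistency); \code{"interaction"} draws only from interaction links
#'   (as used when predicting).
#' @return An object of class \code{"perturbation_split"}: list with matrices
#'   \code{A_r}, \code{A_p}, integer edge matrices \code{E_r}, \code{E_p}
#'   (node index pairs, i < j), \code{node_ids} and \code{seed}.
#' @export
sample_perturbation_split <- function(net, fraction = 0.1, seed = NULL,
                                      pool = c("all", "interaction")) {
  stopifnot(inherits(net, "bilayer"))
  if (!(fraction > 0 && fraction < 1)) stop("fraction must be in (0, 1)")
  pool <- match.arg(pool)
  edges <- edge_pool(net, pool)
  ne <- nrow(edges)
  if (ne == 0) stop("empty edge pool")
  l <- round(fraction * ne)
  if (l < 1) stop("perturbation set would be empty; increase fraction")
  if (!is.null(seed)) set.seed(seed)
  take <- sample.int(ne, l)
  Ep <- edges[take, , drop = FALSE]
  Er <- edges[-take, , drop = FALSE]
  A_r <- net$A
  A_r[Ep] <- 0
  A_r[Ep[, 2:1, drop = FALSE]] <- 0
  A_p <- net$A - A_r
  structure(
    list(A_r = A_r, A_p = A_p, E_r = Er, E_p = Ep,
         node_ids = net$node_ids, seed = seed),
    class = "perturbation_split")
}

symdiff_ids <- function(a, b) union(setdiff(a, b), setdiff(b, a))

#' Align an interaction network to reference id registries
#'
#' Reorders an interaction network to the given lncRNA and miRNA id orders,
#' adding all-zero rows or columns for ids absent from the edge list (RNAs
#' with no recorded interaction).  Useful when an edge list covers only
#' interacting RNAs while the similarity matrices cover the full id
#' universe.
#'
#' @param lm an \code{\link{interaction_network}}.
#' @param lnc_ids,mi_ids reference id orders; must contain every id of
#'   \code{lm}.
#' @return An \code{"lmi_network"} over the reference registries.
#' @export
align_interactions <- function(lm, lnc_ids, mi_ids) {
  stopifnot(inherits(lm, "lmi_network"))
  missing_l <- setdiff(lm$lnc_ids, lnc_ids)
  missing_m <- setdiff(lm$mi_ids, mi_ids)
  if (length(missing_l) || length(missing_m))
    stop("interaction ids absent from the reference registries: ",
         paste(c(missing_l, missing_m), collapse = ", "))
  adj <- matrix(0, length(lnc_ids), length(mi_ids),
                dimnames = list(lnc_ids, mi_ids))
  adj[lm$lnc_ids, lm$mi_ids] <- lm$lm
  interaction_network(adj, lnc_ids, mi_ids)
}
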