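#' Validate a similarity matrix
#'
#' A similarity matrix must be square, have row and column ids, be symmetric
#' to 1e-12, have all entries in [0, 1] (NA allowed for undefined pairs) and
#' unit diagonal.
#'
#' @param s matrix to check.
#' @return \code{s}, invisibly; errors describe the first violated invariant.
#' @export
validate_similarity <- function(s) {
  if (!is.matrix(s) || nrow(s) != ncol(s)) stop("similarity matrix must be square")
  if (is.null(rownames(s)) || !identical(rownames(s), colnames(s)))
    stop("similarity matrix must carry identical row and column ids")
  if (max(abs(s - t(s)), na.rm = TRUE) > 1e-12)
    stop("similarity matrix is not symmetric (tolerance 1e-12)")
  rng <- range(s, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 1)
    stop("similarity values must lie in [0, 1]; found range [",
         signif(rng[1], 4), ", ", signif(rng[2], 4), "]")
  if (any(abs(diag(s) - 1) > 1e-12, na.rm = TRUE))
    stop("similarity diagonal must equal 1")
  invisible(s)
}

#' Expression-profile similarity
#'
#' Pairwise similarity of RNAs from their expression profiles: the absolute
#' value of the Pearson correlation coefficient between profile vectors.
#' Anti-correlated profiles therefore score as similar; the measure is
#' invariant to affine rescaling of any profile.  Pairs where either profile
#' is missing (all-NA row) or has zero variance are left \code{NA}
#' (undefined), to be filled in by \code{\link{integrate_similarity}}.
#'
#' @param profiles numeric matrix, rows = RNA ids (rownames required),
#'   columns = the h expression attributes (h >= 2).  A fully-NA row marks an
#'   RNA without expression data.
#' @return Similarity matrix (see \code{\link{validate_similarity}}) with
#'   \code{NA} for undefined pairs and diagonal forced to 1.
#' @examples
#' x <- rbind(a = c(1, 2, 3), b = c(3, 2, 1), c = c(1, 2, 4))
#' expression_similarity(x)["a", "c"]   # 9 / sqrt(84)
#' @export
expression_similarity <- function(profiles) {
  profiles <- as.matrix(profiles)
  if (is.null(rownames(profiles))) stop("profiles must have rownames (RNA ids)")
  if (anyDuplicated(rownames(profiles))) stop("duplicated profile ids")
  if (ncol(profiles) < 2) stop("degenerate profile length: h must be >= 2")
  present <- rowSums(!is.na(profiles)) > 0
  if (!any(present)) stop("no expression data")
  ps <- suppressWarnings(abs(stats::cor(t(profiles), use = "everything")))
  # zero-variance or missing profiles come back NA/NaN from cor()
  ps[is.nan(ps)] <- NA_real_
  ps[!present, ] <- NA_real_
  ps[, !present] <- NA_real_
  ps <- pmin(ps, 1)           # |r| can exceed 1 by rounding
  diag(ps) <- 1
  dimnames(ps) <- list(rownames(profiles), rownames(profiles))
  validate_similarity(ps)
  ps
}

nw_substitution_matrix <- function(match = 1, mismatch = -1) {
  letters5 <- c("A", "C", "G", "T", "N")
  s <- matrix(mismatch, 5, 5, dimnames = list(letters5, letters5))
  diag(s) <- match
  s["N", "N"] <- mismatch  # ambiguous base never matches, not even itself
  s
}

#' Sequence similarity by global alignment
#'
#' Pairwise similarity of RNAs from their nucleotide sequences via
#' Needleman-Wunsch global alignment.  Sequences are upper-cased and U is
#' normalised to T before alignment; ambiguous bases (N) score as mismatches.
#' The raw alignment score is divided by the longer sequence length and
#' negative values are clipped to 0, giving a score in [0, 1] that equals 1
#' for identical sequences.
#'
#' @param seqs named character vector of nucleotide sequences over
#'   \{A, C, G, T, U, N\}; names are the RNA ids.
#' @param match,mismatch,gap alignment scoring parameters (linear gap
#'   penalty); defaults +1 / -1 / -1.
#' @return Similarity matrix with unit diagonal.
#' @examples
#' seq_sim <- sequence_similarity(c(a = "ACGT", b = "ACGA"))
#' seq_sim["a", "b"]   # (3 matches - 1 mismatch) / 4 = 0.5
#' @export
sequence_similarity <- function(seqs, match = 1, mismatch = -1, gap = -1) {
  if (is.null(names(seqs))) stop("sequences must be named by RNA id")
  if (anyDuplicated(names(seqs))) stop("duplicated sequence ids")
  empty <- !nzchar(seqs) | is.na(seqs)
  if (any(empty))
    stop("empty sequence for id(s): ", paste(names(seqs)[empty], collapse = ", "))
  if (gap > 0) stop("gap penalty must be <= 0")
  seqs <- chartr("uU", "tT", seqs)
  seqs <- toupper(seqs)
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad))
    stop("non-nucleotide characters in sequence(s): ",
         paste(names(seqs)[bad], collapse = ", "))
  sub <- nw_substitution_matrix(match, mismatch)
  n <- length(seqs)
  qs <- diag(1, n)
  dimnames(qs) <- list(names(seqs), names(seqs))
  if (n >= 2) {
    len <- nchar(seqs)
    for (i in seq_len(n - 1)) {
      sc <- Biostrings::pairwiseAlignment(
        rep(seqs[i], n - i), seqs[(i + 1):n], type = "global",
        substitutionMatrix = sub, gapOpening = 0, gapExtension = -gap,
        scoreOnly = TRUE)
      val <- pmin(pmax(sc / pmax(len[i], len[(i + 1):n]), 0), 1)
      qs[i, (i + 1):n] <- val
      qs[(i + 1):n, i] <- val
    }
  }
  validate_similarity(qs)
  qs
}

#' Fuse two similarity networks
#'
#' Combines an expression-profile similarity and a sequence similarity into
#' the final similarity network by the elementwise mean.  Where one input is
#' undefined (\code{NA}, e.g. a missing expression profile) the other is used
#' unchanged, so missing similarity information is complemented rather than
#' halved.
#'
#' @param ps,qs similarity matrices over the same ids in the same order;
#'   \code{NA} entries mark undefined pairs.
#' @return Similarity matrix with no \code{NA}s provided every pair is
#'   defined in at least one input.
#' @export
integrate_similarity <- function(ps, qs) {
  validate_similarity(ps)
  validate_similarity(qs)
  if (!identical(rownames(ps), rownames(qs)))
    stop("id mismatch between similarity matrices: ",
         paste(symdiff_ids(rownames(ps), rownames(qs)), collapse = ", "))
  out <- (ps + qs) / 2
  only_q <- is.na(ps) & !is.na(qs)
  only_p <- !is.na(ps) & is.na(qs)
  out[only_q] <- qs[only_q]
  out[only_p] <- ps[only_p]
  diag(out) <- 1
  validate_similarity(out)
  out
}
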