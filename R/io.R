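#' Read an interaction edge list
#'
#' Reads a two-column TSV of (lncRNA id, miRNA id) pairs into an
#' \code{\link{interaction_network}}.  Duplicate pairs are collapsed to a
#' single interaction; id registries follow first appearance order.
#'
#' @param path TSV file, two tab-separated columns, no header.
#' @return An \code{"lmi_network"} object.
#' @export
read_interactions <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("empty edge list: ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(parts, function(p) length(p) < 2 || !nzchar(p[1]) ||
                        !nzchar(p[2]), logical(1)))
  if (length(bad))
    stop("malformed edge list line ", bad[1], " in ", path)
  lnc <- vapply(parts, `[`, character(1), 1)
  mi <- vapply(parts, `[`, character(1), 2)
  lnc_ids <- unique(lnc)
  mi_ids <- unique(mi)
  adj <- matrix(0, length(lnc_ids), length(mi_ids),
                dimnames = list(lnc_ids, mi_ids))
  adj[cbind(lnc, mi)] <- 1
  interaction_network(adj, lnc_ids, mi_ids)
}

#' Write an interaction edge list
#'
#' @param lm an \code{\link{interaction_network}}.
#' @param path output TSV path.
#' @export
write_interactions <- function(lm, path) {
  stopifnot(inherits(lm, "lmi_network"))
  idx <- which(lm$lm == 1, arr.ind = TRUE)
  df <- data.frame(lnc = lm$lnc_ids[idx[, 1]], mi = lm$mi_ids[idx[, 2]])
  df <- df[order(match(df$lnc, lm$lnc_ids), match(df$mi, lm$mi_ids)), ]
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read / write a dense similarity matrix
#'
#' Dense TSV with an id header row and id first column.  On read the matrix
#' is checked against the similarity invariants (square, symmetric, values
#' in [0, 1], unit diagonal); round-trips are lossless to full double
#' precision.
#'
#' @param path TSV file path.
#' @return \code{read_similarity}: the validated similarity matrix.
#' @export
read_similarity <- function(path) {
  s <- read_matrix_tsv(path)
  validate_similarity(s)
  s
}

#' @param s similarity (or general square) matrix with dimnames.
#' @rdname read_similarity
#' @export
write_similarity <- function(s, path) {
  validate_similarity(s)
  write_matrix_tsv(s, path)
}

read_matrix_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, row.names = 1,
                          check.names = FALSE)
  m <- as.matrix(df)
  if (nrow(m) != ncol(m)) stop("matrix in ", path, " is not square")
  m
}

write_matrix_tsv <- function(m, path) {
  df <- data.frame(id = rownames(m), m, check.names = FALSE)
  utils::write.table(format(df, digits = 17, trim = TRUE, scientific = TRUE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write / read a bilayer matrix
#'
#' Dense TSV export of the full bilayer matrix (ids as header row/column).
#'
#' @param net a \code{"bilayer"} object (write) or file path (read).
#' @param path output path.
#' @export
write_bilayer <- function(net, path) {
  stopifnot(inherits(net, "bilayer"))
  write_matrix_tsv(net$A, path)
}

#' Read an expression-profile table
#'
#' TSV with header; first column = RNA id, remaining columns numeric
#' expression attributes.  Empty cells become \code{NA}; a fully-NA row
#' marks an RNA without expression data.
#'
#' @param path TSV file path.
#' @return Numeric matrix with RNA ids as rownames, ready for
#'   \code{\link{expression_similarity}}.
#' @export
read_expression <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, row.names = 1,
                          check.names = FALSE)
  m <- as.matrix(df)
  if (!is.numeric(m)) stop("non-numeric expression values in ", path)
  if (ncol(m) < 2) stop("degenerate profile length: h must be >= 2")
  m
}

#' Read nucleotide sequences from FASTA
#'
#' @param path FASTA file.
#' @return Named character vector of sequences, suitable for
#'   \code{\link{sequence_similarity}}.
#' @export
read_sequences <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  out <- as.character(ss)
  names(out) <- sub("\\s.*$", "", names(ss))
  out
}
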