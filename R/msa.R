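#' Effective number of sequences (Neff proxy)
#'
#' Sequence-redundancy weighting at an identity threshold, normalized by the
#' square root of the protein length: each sequence is weighted by
#' 1 / (number of sequences, including itself, whose pairwise identity with
#' it is at or above `identity_threshold`), and
#' `neff = sum(weights) / sqrt(L)`. This is a documented proxy for the
#' aligner-reported Neff ("effective number of sequences, length weighted"):
#' it is monotone in alignment diversity, which is what Neff-stratified
#' analyses need; absolute values are not comparable to any external tool.
#'
#' Pairwise identity is the fraction of aligned columns with identical
#' characters (gap characters compare like any other character).
#'
#' @param msa character vector of aligned sequences (equal lengths), or a
#'   list of single characters per position as returned by FASTA readers.
#' @param L protein length used for the normalization; defaults to the
#'   alignment width.
#' @param identity_threshold clustering threshold (default 0.8).
#' @param protein_id identifier.
#' @return A list of class `msa_stats` with `protein_id`, `n_sequences`,
#'   `neff`.
#' @export
compute_neff <- function(msa, L = NULL, identity_threshold = 0.8,
                         protein_id = "msa") {
  if (is.list(msa)) msa <- vapply(msa, function(s) paste(s, collapse = ""), "")
  msa <- toupper(as.character(msa))
  n <- length(msa)
  if (n == 0L) stop_param("compute_neff: empty alignment")
  width <- unique(nchar(msa))
  if (length(width) != 1L)
    stop_param("compute_neff: aligned sequences must have equal length")
  if (is.null(L)) L <- width
  if (!is_count(L) || L < 1) stop_param("compute_neff: L must be a positive integer")
  chars <- matrix(unlist(strsplit(msa, "")), nrow = n, byrow = TRUE)
  # pairwise identity fractions, O(n^2 * width)
  nident <- matrix(0L, n, n)
  for (a in seq_len(n)) {
    eq <- chars == matrix(chars[a, ], n, width, byrow = TRUE)
    nident[a, ] <- rowSums(eq)
  }
  ident <- nident / width
  weights <- 1 / rowSums(ident >= identity_threshold)
  structure(list(protein_id = as.character(protein_id),
                 n_sequences = n,
                 neff = sum(weights) / sqrt(L)),
            class = "msa_stats")
}

#' @export
print.msa_stats <- function(x, ...) {
  cat(sprintf("msa_stats '%s': %d sequences, Neff = %.4f\n",
              x$protein_id, x$n_sequences, x$neff))
  invisible(x)
}

#' Read an aligned FASTA / A3M file as a character vector
#'
#' A3M lowercase insert states are removed so all sequences share the match
#' columns.
#'
#' @param source path to the alignment.
#' @return Character vector of aligned sequences (names = FASTA headers).
#' @export
read_alignment <- function(source) {
  seqs <- seqinr::read.fasta(source, seqtype = "AA", as.string = TRUE,
                             forceDNAtolower = FALSE)
  out <- vapply(seqs, function(s) gsub("[a-z]", "", as.character(s)[1]), "")
  names(out) <- names(seqs)
  out
}
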