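#' Ground-truth contact map
#'
#' A `contact_map` is the set of unordered residue pairs (i < j) in contact,
#' restricted to sequence separation `j - i >= separation_min`, together with
#' the mask of residue indices whose coordinates are absent. Pairs touching a
#' masked index are never included.
#'
#' @param L region length (largest residue index).
#' @param pairs two-column integer matrix of contacting pairs (any order;
#'   normalized to i < j).
#' @param separation_min minimum sequence separation (default 6, i.e.
#'   `|i - j| > 5`).
#' @param mask integer vector of residue indices without coordinates.
#' @return An object of class `contact_map`.
#' @export
contact_map <- function(L, pairs, separation_min = 6L, mask = integer()) {
  if (!is_count(L) || L < 1) stop_param("contact_map: L must be a positive integer")
  if (!is_count(separation_min) || separation_min < 1)
    stop_param("contact_map: separation_min must be >= 1")
  pairs <- if (is.null(pairs) || length(pairs) == 0L)
    cbind(i = integer(), j = integer())
  else normalize_pairs(pairs[, 1], pairs[, 2])
  mask <- sort(unique(as.integer(mask)))
  if (nrow(pairs)) {
    if (any(pairs < 1L) || any(pairs > L))
      stop_param("contact_map: pair index outside [1, %d]", L)
    if (any(pairs[, 2] - pairs[, 1] < separation_min))
      stop_param("contact_map: pair violates separation_min = %d", separation_min)
    if (any(pairs[, 1] %in% mask) || any(pairs[, 2] %in% mask))
      stop_param("contact_map: pair touches a masked index")
    pairs <- pairs[!duplicated(pair_key(pairs[, 1], pairs[, 2], L)), , drop = FALSE]
    pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
  }
  structure(list(L = as.integer(L), pairs = pairs,
                 separation_min = as.integer(separation_min), mask = mask),
            class = "contact_map")
}

#' @export
print.contact_map <- function(x, ...) {
  cat(sprintf("contact_map: L = %d, %d contacts (separation >= %d), %d masked residues\n",
              x$L, nrow(x$pairs), x$separation_min, length(x$mask)))
  invisible(x)
}

#' Derive true contacts from coordinates
#'
#' A contact is a residue pair whose representative atoms (C-beta; C-alpha
#' for glycine) lie at Euclidean distance less than or equal to `cutoff`
#' (the 8 Angstrom boundary is inclusive) and whose sequence separation
#' exceeds five residues (`j - i >= separation_min`). Residues with absent
#' coordinates are masked out of the pairing but keep their index.
#'
#' @param rs a [residue_set()].
#' @param cutoff contact distance threshold in Angstrom (default 8).
#' @param separation_min minimum sequence separation (default 6).
#' @return A [contact_map()] whose `L` is the largest residue index; indices
#'   missing from `rs` entirely (chain gaps) are masked.
#' @export
true_contacts <- function(rs, cutoff = 8.0, separation_min = 6L) {
  stopifnot(inherits(rs, "residue_set"))
  if (!is.numeric(cutoff) || length(cutoff) != 1L || cutoff <= 0)
    stop_param("true_contacts: cutoff must be > 0")
  if (!is_count(separation_min) || separation_min < 1)
    stop_param("true_contacts: separation_min must be >= 1")
  L <- max(rs$seq_index)
  present <- !is.na(rs$x)
  mask <- sort(union(rs$seq_index[!present], setdiff(seq_len(L), rs$seq_index)))
  ok <- rs[present, , drop = FALSE]
  if (nrow(ok) < 2L)
    return(contact_map(L, NULL, separation_min, mask))
  d <- as.matrix(stats::dist(cbind(ok$x, ok$y, ok$z)))
  idx <- ok$seq_index
  sel <- which(upper.tri(d) & d <= cutoff, arr.ind = TRUE)
  if (nrow(sel)) {
    i <- idx[sel[, 1]]
    j <- idx[sel[, 2]]
    keep <- abs(j - i) >= separation_min
    pairs <- normalize_pairs(i[keep], j[keep])
  } else pairs <- NULL
  contact_map(L, pairs, separation_min, mask)
}

#' Test membership of pairs in a contact map
#'
#' @param cm a [contact_map()].
#' @param i,j integer vectors of residue indices (any order within a pair).
#' @return Logical vector: is each (i, j) a contact?
#' @export
is_contact <- function(cm, i, j) {
  stopifnot(inherits(cm, "contact_map"))
  p <- normalize_pairs(i, j)
  pair_key(p[, 1], p[, 2], cm$L) %in%
    pair_key(cm$pairs[, 1], cm$pairs[, 2], cm$L)
}
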