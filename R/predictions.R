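#' Scored contact predictions
#'
#' @param protein_id character scalar.
#' @param L region length.
#' @param i,j residue indices (normalized so i < j).
#' @param score prediction scores in [0, 1].
#' @return An object of class `prediction_set`: a data frame with columns
#'   `i`, `j`, `score`, plus `protein_id` and `L` attributes.
#' @export
prediction_set <- function(protein_id, L, i, j, score) {
  if (!is_count(L) || L < 1) stop_param("prediction_set: L must be a positive integer")
  p <- normalize_pairs(i, j)
  score <- as.numeric(score)
  if (length(score) != nrow(p))
    stop_param("prediction_set: score length mismatch")
  if (nrow(p)) {
    if (any(p[, 1] == p[, 2])) stop_param("prediction_set: self-pair i == j")
    if (any(p < 1L) || any(p > L))
      stop_param("prediction_set: pair index outside [1, %d]", L)
    if (any(!is.finite(score)) || any(score < 0) || any(score > 1))
      stop_param("prediction_set: scores must lie in [0, 1]")
    dup <- duplicated(pair_key(p[, 1], p[, 2], L))
    if (any(dup))
      stop_param("prediction_set: duplicate pair (%d, %d)",
                 p[which(dup)[1], 1], p[which(dup)[1], 2])
  }
  ps <- data.frame(i = p[, 1], j = p[, 2], score = score)
  attr(ps, "protein_id") <- as.character(protein_id)
  attr(ps, "L") <- as.integer(L)
  class(ps) <- c("prediction_set", "data.frame")
  ps
}

#' @export
print.prediction_set <- function(x, ...) {
  cat(sprintf("prediction_set '%s': %d scored pairs, L = %d\n",
              attr(x, "protein_id"), nrow(x), attr(x, "L")))
  invisible(x)
}

#' Read a CASP-RR contact list
#'
#' Expects data lines of the form `i j d_low d_high p`; header lines
#' (PFRMAT, TARGET, MODEL, sequence lines) are skipped. Pairs are normalized
#' to i < j.
#'
#' @param source path to the RR file.
#' @param L region length; indices outside `[1, L]` are rejected.
#' @param protein_id identifier (default: file basename).
#' @return A [prediction_set()].
#' @export
read_rr <- function(source, L, protein_id = NULL) {
  lines <- readLines(source, warn = FALSE)
  lines <- trimws(lines)
  data <- grepl("^[0-9]+\\s+[0-9]+\\s", lines)
  fields <- strsplit(lines[data], "\\s+")
  nf <- lengths(fields)
  if (any(nf != 5L))
    stop_param("read_rr: line '%s' does not have 5 fields",
               lines[data][which(nf != 5L)[1]])
  m <- matrix(suppressWarnings(as.numeric(unlist(fields))), ncol = 5L, byrow = TRUE)
  if (any(is.na(m)))
    stop_param("read_rr: non-numeric field in %s", source)
  if (any(m[, 5] < 0 | m[, 5] > 1))
    stop_param("read_rr: probability outside [0, 1] on line '%s'",
               lines[data][which(m[, 5] < 0 | m[, 5] > 1)[1]])
  if (any(m[, 1] < 1 | m[, 1] > L | m[, 2] < 1 | m[, 2] > L))
    stop_param("read_rr: residue index outside [1, %d]", L)
  prediction_set(protein_id %||% sub("\\.rr$", "", basename(source)),
                 L, m[, 1], m[, 2], m[, 5])
}

#' Write a prediction set in CASP-RR format
#'
#' @param ps a [prediction_set()].
#' @param path output file.
#' @param d_low,d_high distance range written on every line (default 0 and 8).
#' @return `path`, invisibly.
#' @export
write_rr <- function(ps, path, d_low = 0, d_high = 8) {
  stopifnot(inherits(ps, "prediction_set"))
  ord <- order(-ps$score, ps$i, ps$j)
  writeLines(sprintf("%d %d %g %g %.6f", ps$i[ord], ps$j[ord],
                     d_low, d_high, ps$score[ord]), path)
  invisible(path)
}

#' Binned pairwise distance distributions (distogram)
#'
#' `bin_edges` are strictly increasing distances in Angstrom defining
#' half-open bins `[e_k, e_{k+1})` plus one terminal bin beyond the last
#' edge, so `length(bin_edges)` bins in total. The default convention is 36
#' half-Angstrom bins from 2 to 20 Angstrom plus the terminal bin (37 bins).
#'
#' @param L region length.
#' @param i,j residue indices of each pair.
#' @param probs matrix, one row per pair, one column per bin; each row must
#'   sum to 1 within 1e-6.
#' @param bin_edges increasing bin-edge distances (Angstrom).
#' @return An object of class `distogram`.
#' @export
distogram <- function(L, i, j, probs, bin_edges = default_bin_edges()) {
  if (!is_count(L) || L < 1) stop_param("distogram: L must be a positive integer")
  bin_edges <- as.numeric(bin_edges)
  if (length(bin_edges) < 2L || any(diff(bin_edges) <= 0))
    stop_param("distogram: bin_edges must be strictly increasing")
  probs <- as.matrix(probs)
  if (ncol(probs) != length(bin_edges))
    stop_param("distogram: expected %d bins (one per edge, incl. terminal), got %d",
               length(bin_edges), ncol(probs))
  p <- normalize_pairs(i, j)
  if (nrow(p) != nrow(probs)) stop_param("distogram: pair/probs length mismatch")
  if (any(p < 1L) || any(p > L)) stop_param("distogram: index outside [1, %d]", L)
  sums <- rowSums(probs)
  if (any(abs(sums - 1) > 1e-6))
    stop_param("distogram: per-pair probabilities must sum to 1 (worst deviation %.2g)",
               max(abs(sums - 1)))
  structure(list(L = as.integer(L), i = p[, 1], j = p[, 2],
                 probs = probs, bin_edges = bin_edges),
            class = "distogram")
}

#' Default distogram bin edges: 2 to 20 Angstrom in 0.5 steps
#' @return Numeric vector of 37 edges (36 finite bins + terminal bin).
#' @export
default_bin_edges <- function() seq(2, 20, by = 0.5)

#' Read a distogram text container
#'
#' Format: a header line `#edges: e1,e2,...`, then one line per pair
#' `i j p1 ... pK` with K = number of edges (the last probability belongs to
#' the terminal beyond-last-edge bin).
#'
#' @param source path.
#' @return A [distogram()].
#' @export
read_distogram <- function(source) {
  lines <- readLines(source, warn = FALSE)
  hdr <- grep("^#edges:", lines, value = TRUE)
  if (length(hdr) != 1L)
    stop_param("read_distogram: missing '#edges:' header in %s", source)
  edges <- as.numeric(strsplit(sub("^#edges:\\s*", "", hdr), ",")[[1]])
  body <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  fields <- strsplit(trimws(body), "\\s+")
  m <- matrix(suppressWarnings(as.numeric(unlist(fields))),
              nrow = length(fields), byrow = TRUE)
  if (any(is.na(m))) stop_param("read_distogram: non-numeric field in %s", source)
  Ldecl <- grep("^#L:", lines, value = TRUE)
  L <- if (length(Ldecl)) as.integer(sub("^#L:\\s*", "", Ldecl[1]))
       else max(m[, 1:2])
  distogram(L, m[, 1], m[, 2], m[, -(1:2), drop = FALSE], edges)
}

#' Write a distogram text container
#' @param d a [distogram()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_distogram <- function(d, path) {
  stopifnot(inherits(d, "distogram"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("#L: %d", d$L),
               paste0("#edges: ", paste(format(d$bin_edges, trim = TRUE), collapse = ","))),
             con)
  writeLines(paste(d$i, d$j, apply(d$probs, 1, function(r)
    paste(formatC(r, format = "g"), collapse = " "))), con)
  invisible(path)
}

#' Convert a distogram to contact probabilities
#'
#' The contact score of a pair is the summed probability of all distance
#' bins whose upper edge is at or below the cutoff. The cutoff must coincide
#' with a bin edge: the rule sums whole bins, so a cutoff inside a bin is an
#' error rather than a silent interpolation.
#'
#' @param d a [distogram()].
#' @param cutoff contact distance in Angstrom (default 8); must equal one of
#'   `d$bin_edges`.
#' @param protein_id identifier for the resulting prediction set.
#' @return A [prediction_set()] with `score(i, j) = P(distance <= cutoff)`.
#' @export
distogram_to_contacts <- function(d, cutoff = 8.0, protein_id = "distogram") {
  stopifnot(inherits(d, "distogram"))
  hit <- which(abs(d$bin_edges - cutoff) < 1e-9)
  if (length(hit) != 1L)
    stop_param("distogram_to_contacts: cutoff %.3f is not a bin edge (edges %s ... %s)",
               cutoff, format(d$bin_edges[1]), format(d$bin_edges[length(d$bin_edges)]))
  # bins 1..(hit-1) have upper edge <= cutoff; terminal bin never counts
  score <- if (hit == 1L) rep(0, length(d$i))
           else rowSums(d$probs[, seq_len(hit - 1L), drop = FALSE])
  prediction_set(protein_id, d$L, d$i, d$j, clip01(score))
}
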