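#' Repeat region annotation
#'
#' A repeat region with its ordered unit spans, in the RepeatsDB convention:
#' 1-based inclusive coordinates, non-overlapping sorted units contained in
#' the region, a structural class label (e.g. `"III.1"` alpha-solenoid,
#' `"IV.4"` closed beta-propeller, `"V.1"` beads-on-a-string), and optional
#' insertion spans not belonging to any unit.
#'
#' @param protein_id character scalar.
#' @param region length-2 integer vector `(start, end)`.
#' @param units two-column matrix (or list of length-2 vectors) of unit
#'   spans.
#' @param repeat_class class/subclass label.
#' @param insertions optional spans outside all units.
#' @return An object of class `repeat_annotation`.
#' @export
repeat_annotation <- function(protein_id, region, units, repeat_class = "III.1",
                              insertions = NULL) {
  region <- as.integer(region)
  if (length(region) != 2L || region[1] > region[2])
    stop_param("repeat_annotation: region must be (start <= end)")
  units <- span_matrix(units)
  if (nrow(units) == 0L) stop_param("repeat_annotation: at least one unit required")
  if (any(units[, 1] > units[, 2]))
    stop_param("repeat_annotation: unit start > end")
  units <- units[order(units[, 1]), , drop = FALSE]
  if (nrow(units) > 1L && any(units[-1L, 1] <= units[-nrow(units), 2]))
    stop_param("repeat_annotation: units overlap")
  if (units[1, 1] < region[1] || units[nrow(units), 2] > region[2])
    stop_param("repeat_annotation: units must lie inside the region")
  insertions <- if (is.null(insertions)) cbind(start = integer(), end = integer())
                else span_matrix(insertions)
  structure(list(protein_id = as.character(protein_id), region = region,
                 units = units, repeat_class = as.character(repeat_class),
                 insertions = insertions),
            class = "repeat_annotation")
}

span_matrix <- function(x) {
  if (is.list(x)) x <- do.call(rbind, x)
  x <- matrix(as.integer(x), ncol = 2L)
  colnames(x) <- c("start", "end")
  x
}

#' @export
print.repeat_annotation <- function(x, ...) {
  cat(sprintf("repeat_annotation '%s' [%s]: region %d-%d, %d units%s\n",
              x$protein_id, x$repeat_class, x$region[1], x$region[2],
              nrow(x$units),
              if (nrow(x$insertions)) sprintf(", %d insertions", nrow(x$insertions)) else ""))
  invisible(x)
}

# unit index (1..n_units) per residue position; 0 for residues outside units
unit_index <- function(ann, idx) {
  u <- integer(length(idx))
  for (k in seq_len(nrow(ann$units)))
    u[idx >= ann$units[k, 1] & idx <= ann$units[k, 2]] <- k
  u
}

#' Classify residue pairs as intra-unit, inter-unit, or unclassified
#'
#' A pair is `INTRA` when both residues fall in the same repeat unit,
#' `INTER` when they fall in two different units, and `UNCLASSIFIED` when
#' either residue lies outside all units (linkers, insertions). Unclassified
#' pairs are excluded from the stratified precision analysis.
#'
#' @param ann a [repeat_annotation()].
#' @param i,j residue indices (vectorized; `i[k] != j[k]`).
#' @return Character vector in `{"INTRA", "INTER", "UNCLASSIFIED"}`.
#' @export
classify_pair <- function(ann, i, j) {
  stopifnot(inherits(ann, "repeat_annotation"))
  i <- as.integer(i); j <- as.integer(j)
  if (any(i == j)) stop_param("classify_pair: i == j")
  idx <- c(i, j)
  if (any(idx < ann$region[1] | idx > ann$region[2]))
    stop_param("classify_pair: index outside region %d-%d",
               ann$region[1], ann$region[2])
  ui <- unit_index(ann, i)
  uj <- unit_index(ann, j)
  ifelse(ui == 0L | uj == 0L, "UNCLASSIFIED",
         ifelse(ui == uj, "INTRA", "INTER"))
}

#' Count true contacts by intra/inter-unit class
#'
#' @param cm a [contact_map()].
#' @param ann a [repeat_annotation()] for the same protein.
#' @return Named integer vector `(n_intra, n_inter, n_unclassified)`; the
#'   three counts always partition the contact total.
#' @export
count_true_by_class <- function(cm, ann) {
  stopifnot(inherits(cm, "contact_map"))
  if (nrow(cm$pairs) == 0L)
    return(c(n_intra = 0L, n_inter = 0L, n_unclassified = 0L))
  cls <- classify_pair(ann, cm$pairs[, 1], cm$pairs[, 2])
  c(n_intra = sum(cls == "INTRA"), n_inter = sum(cls == "INTER"),
    n_unclassified = sum(cls == "UNCLASSIFIED"))
}

#' Select the representative unit window
#'
#' Returns the span of `k` consecutive units whose combined span contains
#' the fewest residues outside any unit (insertions/linkers), with ties
#' broken by earliest sequence position. This formalizes picking
#' representative single-unit (`k = 1`) or double-unit (`k = 2`) fragments
#' while minimising the presence of insertions.
#'
#' @param ann a [repeat_annotation()].
#' @param k number of consecutive units (1 or 2 in the standard splits).
#' @return Integer vector `(start, end)`, 1-based inclusive, with attribute
#'   `units` giving the chosen unit indices.
#' @export
extract_unit_windows <- function(ann, k = 1L) {
  stopifnot(inherits(ann, "repeat_annotation"))
  n <- nrow(ann$units)
  if (!is_count(k) || k < 1) stop_param("extract_unit_windows: k must be >= 1")
  if (n < k) stop_param("extract_unit_windows: annotation has %d units, need %d", n, k)
  best <- NULL
  best_gap <- Inf
  for (s in seq_len(n - k + 1L)) {
    span <- unname(c(ann$units[s, 1], ann$units[s + k - 1L, 2]))
    covered <- sum(ann$units[s:(s + k - 1L), 2] - ann$units[s:(s + k - 1L), 1] + 1L)
    gap <- (span[2] - span[1] + 1L) - covered
    if (gap < best_gap) {
      best_gap <- gap
      best <- structure(span, units = s:(s + k - 1L), n_insertion_residues = gap)
    }
  }
  best
}

#' Read repeat annotations from a tab-separated file
#'
#' One row per region with columns `protein_id`, `region_start`,
#' `region_end`, `class`, `units`, `insertions`; spans are comma-separated
#' `start-end` tokens, `insertions` may be `.`.
#'
#' @param source path.
#' @return Named list of [repeat_annotation()] objects (by protein_id).
#' @export
read_annotations <- function(source) {
  tab <- utils::read.table(source, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, comment.char = "#")
  need <- c("protein_id", "region_start", "region_end", "class", "units")
  if (!all(need %in% names(tab)))
    stop_param("read_annotations: missing columns: %s",
               paste(setdiff(need, names(tab)), collapse = ", "))
  parse_spans <- function(s) {
    if (is.na(s) || s == "." || s == "") return(NULL)
    do.call(rbind, lapply(strsplit(s, ",")[[1]], function(tok) {
      se <- as.integer(strsplit(tok, "-")[[1]])
      if (length(se) != 2L || any(is.na(se)))
        stop_param("read_annotations: malformed span '%s'", tok)
      se
    }))
  }
  anns <- lapply(seq_len(nrow(tab)), function(r)
    repeat_annotation(tab$protein_id[r],
                      c(tab$region_start[r], tab$region_end[r]),
                      parse_spans(tab$units[r]), tab$class[r],
                      if ("insertions" %in% names(tab))
                        parse_spans(tab$insertions[r]) else NULL))
  names(anns) <- tab$protein_id
  anns
}

#' Write repeat annotations to a tab-separated file
#' @param anns a [repeat_annotation()] or list of them.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(anns, path) {
  if (inherits(anns, "repeat_annotation")) anns <- list(anns)
  fmt_spans <- function(m) if (nrow(m) == 0L) "." else
    paste(sprintf("%d-%d", m[, 1], m[, 2]), collapse = ",")
  lines <- c(paste(c("protein_id", "region_start", "region_end", "class",
                     "units", "insertions"), collapse = "\t"),
             vapply(anns, function(a)
               paste(c(a$protein_id, a$region[1], a$region[2], a$repeat_class,
                       fmt_spans(a$units), fmt_spans(a$insertions)),
                     collapse = "\t"), ""))
  writeLines(lines, path)
  invisible(path)
}
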