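#' Per-residue representative-atom coordinates
#'
#' A `residue_set` holds one representative atom per residue: the beta carbon,
#' or the alpha carbon for glycine (which has no C-beta). Residues lacking
#' both atoms keep their place in the numbering with absent (`NA`)
#' coordinates, so downstream unit spans remain valid without renumbering.
#'
#' @param protein_id character scalar identifying the protein/chain.
#' @param seq_index strictly increasing 1-based residue numbers.
#' @param aa one-letter amino-acid codes (same length as `seq_index`).
#' @param coords numeric matrix with 3 columns (x, y, z in Angstrom); rows
#'   with any `NA` mark residues with absent coordinates.
#'
#' @return An object of class `residue_set`: a data frame with columns
#'   `seq_index`, `aa`, `x`, `y`, `z` and a `protein_id` attribute.
#' @export
residue_set <- function(protein_id, seq_index, aa, coords) {
  seq_index <- as.integer(seq_index)
  if (length(seq_index) == 0L) stop_param("residue_set: no residues")
  if (any(diff(seq_index) <= 0L))
    stop_param("residue_set: seq_index must be strictly increasing")
  coords <- matrix(as.numeric(coords), ncol = 3L)
  if (nrow(coords) != length(seq_index) || length(aa) != length(seq_index))
    stop_param("residue_set: seq_index, aa and coords lengths differ")
  bad <- is.finite(coords[, 1]) & is.finite(coords[, 2]) & is.finite(coords[, 3])
  coords[!bad, ] <- NA_real_
  rs <- data.frame(seq_index = seq_index, aa = as.character(aa),
                   x = coords[, 1], y = coords[, 2], z = coords[, 3],
                   stringsAsFactors = FALSE)
  attr(rs, "protein_id") <- as.character(protein_id)
  class(rs) <- c("residue_set", "data.frame")
  rs
}

#' @export
print.residue_set <- function(x, ...) {
  cat(sprintf("residue_set '%s': %d residues (%d with coordinates), range %d-%d\n",
              attr(x, "protein_id"), nrow(x), sum(!is.na(x$x)),
              min(x$seq_index), max(x$seq_index)))
  invisible(x)
}

#' Read representative-atom coordinates
#'
#' Reads either PDB ATOM records (via \pkg{bio3d}) or the plain tabular
#' coordinate format written by [write_coordinate_table()]. The
#' representative atom is CB, falling back to CA for glycine; residues with
#' neither atom are kept with absent coordinates. For PDB input, the first
#' alternate location is kept and insertion-coded residues are skipped with
#' a warning.
#'
#' @param source path to a PDB file or a tab-separated coordinate table
#'   (columns `protein_id seq_index aa x y z`, `.` for absent coordinates).
#' @param chain chain identifier (PDB input only; default `"A"`).
#' @param format `"auto"` (sniff), `"pdb"` or `"table"`.
#' @return A [residue_set()].
#' @export
read_coordinates <- function(source, chain = "A", format = c("auto", "pdb", "table")) {
  format <- match.arg(format)
  if (!file.exists(source)) stop_param("read_coordinates: no such file: %s", source)
  if (format == "auto") {
    head_lines <- readLines(source, n = 50L, warn = FALSE)
    format <- if (any(grepl("^(ATOM|HETATM|HEADER|MODEL|REMARK)", head_lines)))
      "pdb" else "table"
  }
  if (format == "pdb") read_coordinates_pdb(source, chain)
  else read_coordinate_table(source)
}

read_coordinates_pdb <- function(source, chain) {
  pdb <- tryCatch(suppressWarnings(bio3d::read.pdb(source, verbose = FALSE)),
                  error = function(e)
                    stop_param("read_coordinates: unparseable PDB '%s': %s",
                               source, conditionMessage(e)))
  at <- pdb$atom
  at <- at[at$type == "ATOM" & at$chain %in% chain, , drop = FALSE]
  if (nrow(at) == 0L)
    stop_param("read_coordinates: chain '%s' has no ATOM records in %s",
               chain, source)
  # keep first altloc only
  alt_keep <- is.na(at$alt) | at$alt %in% c("", "A", "1")
  at <- at[alt_keep, , drop = FALSE]
  ins <- !(is.na(at$insert) | at$insert == "")
  if (any(ins)) {
    warning(sprintf("read_coordinates: skipping %d insertion-coded residues in %s",
                    length(unique(at$resno[ins])), source))
    at <- at[!ins, , drop = FALSE]
  }
  resno <- sort(unique(at$resno))
  n <- length(resno)
  coords <- matrix(NA_real_, n, 3L)
  aa <- character(n)
  for (k in seq_len(n)) {
    rows <- at[at$resno == resno[k], , drop = FALSE]
    aa3 <- rows$resid[1]
    aa[k] <- bio3d::aa321(aa3)
    hit <- rows[rows$elety == "CB", , drop = FALSE]
    if (nrow(hit) == 0L) hit <- rows[rows$elety == "CA", , drop = FALSE]
    if (nrow(hit) > 0L)
      coords[k, ] <- as.numeric(hit[1L, c("x", "y", "z")])
  }
  pid <- sub("\\.(pdb|ent)$", "", basename(source))
  residue_set(paste0(pid, "_", chain[1]), resno, aa, coords)
}

read_coordinate_table <- function(source) {
  tab <- tryCatch(
    utils::read.table(source, sep = "\t", header = FALSE, comment.char = "#",
                      stringsAsFactors = FALSE,
                      col.names = c("protein_id", "seq_index", "aa", "x", "y", "z"),
                      colClasses = c("character", "integer", "character",
                                     "character", "character", "character")),
    error = function(e)
      stop_param("read_coordinates: unparseable coordinate table '%s': %s",
                 source, conditionMessage(e)))
  if (nrow(tab) == 0L) stop_param("read_coordinates: empty coordinate table %s", source)
  num <- function(v) suppressWarnings(ifelse(v == ".", NA_real_, as.numeric(v)))
  x <- num(tab$x); y <- num(tab$y); z <- num(tab$z)
  bad <- which((tab$x != "." & is.na(x)) | (tab$y != "." & is.na(y)) |
                 (tab$z != "." & is.na(z)))
  if (length(bad))
    stop_param("read_coordinates: malformed coordinate on line %d of %s",
               bad[1], source)
  residue_set(tab$protein_id[1], tab$seq_index, tab$aa, cbind(x, y, z))
}

#' Write a residue set as a tabular coordinate fixture
#'
#' @param rs a [residue_set()].
#' @param path output file; tab-separated, `.` for absent coordinates.
#' @return `path`, invisibly.
#' @export
write_coordinate_table <- function(rs, path) {
  stopifnot(inherits(rs, "residue_set"))
  fmt <- function(v) ifelse(is.na(v), ".", formatC(v, format = "f", digits = 3))
  lines <- sprintf("%s\t%d\t%s\t%s\t%s\t%s", attr(rs, "protein_id"),
                   rs$seq_index, rs$aa, fmt(rs$x), fmt(rs$y), fmt(rs$z))
  writeLines(lines, path)
  invisible(path)
}
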