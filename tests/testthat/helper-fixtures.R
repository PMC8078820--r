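# shared fixtures and independent brute-force oracles

# a residue set with random coordinates in a box; some residues absent
random_residue_set <- function(L, absent_frac = 0, box = 20) {
  coords <- matrix(runif(3 * L, 0, box), L, 3)
  if (absent_frac > 0)
    coords[runif(L) < absent_frac, ] <- NA_real_
  residue_set("rand", seq_len(L), rep("A", L), coords)
}

# O(L^2) scan straight from the contact definition, independent of
# true_contacts' vectorized path
brute_force_contacts <- function(rs, cutoff = 8.0, separation_min = 6L) {
  out <- NULL
  for (a in seq_len(nrow(rs) - 1L)) for (b in (a + 1L):nrow(rs)) {
    if (is.na(rs$x[a]) || is.na(rs$x[b])) next
    i <- rs$seq_index[a]; j <- rs$seq_index[b]
    if (j - i < separation_min) next
    d <- sqrt((rs$x[a] - rs$x[b])^2 + (rs$y[a] - rs$y[b])^2 +
                (rs$z[a] - rs$z[b])^2)
    if (d <= cutoff) out <- rbind(out, c(i, j))
  }
  out
}

pairs_to_string <- function(p) {
  if (is.null(p) || nrow(p) == 0L) return(character())
  sort(paste(p[, 1], p[, 2], sep = "-"))
}

# fixed-width PDB ATOM record
pdb_line <- function(serial, atom, resname, chain, resno, x, y, z,
                     alt = " ", icode = " ") {
  sprintf("ATOM  %5d %-4s%s%-3s %s%4d%s   %8.3f%8.3f%8.3f%6.2f%6.2f           C",
          serial, paste0(" ", atom), alt, resname, chain, resno, icode,
          x, y, z, 1, 0)
}

# two-unit annotation over residues 1..60
two_unit_ann <- function() repeat_annotation("p1", c(1, 60),
                                             rbind(c(1, 30), c(31, 60)))

# pairwise-identity Neff oracle: direct O(N^2) double loop
brute_force_neff <- function(seqs, L, thr = 0.8) {
  n <- length(seqs)
  ch <- strsplit(seqs, "")
  w <- numeric(n)
  for (a in seq_len(n)) {
    cnt <- 0L
    for (b in seq_len(n))
      if (mean(ch[[a]] == ch[[b]]) >= thr) cnt <- cnt + 1L
    w[a] <- 1 / cnt
  }
  sum(w) / sqrt(L)
}
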