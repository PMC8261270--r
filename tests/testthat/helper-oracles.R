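# Independent oracles and in-code fixture builders shared across tests.
# These deliberately avoid the package's own vectorized code paths.

# entropy of a count vector, bits
oracle_entropy <- function(counts) {
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log2(p))
}

# information gain of one already-discretized feature by direct counting
# over the value x class contingency table
oracle_ig <- function(values, labels) {
  n <- length(labels)
  H <- oracle_entropy(table(labels))
  Hc <- 0
  for (v in unique(values)) {
    sel <- values == v
    Hc <- Hc + (sum(sel) / n) * oracle_entropy(table(labels[sel]))
  }
  max(H - Hc, 0)
}

# exhaustive all-pairs minimum distance, plain double loop
oracle_min_dist <- function(L, R) {
  best <- Inf
  for (i in seq_len(nrow(L)))
    for (j in seq_len(nrow(R))) {
      d <- sqrt(sum((L[i, ] - R[j, ])^2))
      if (d < best) best <- d
    }
  best
}

random_spectrum <- function(n_modes, id = "mol", wmax = 4500) {
  vib_spectrum(runif(n_modes, 0, wmax), rexp(n_modes), id)
}

# small labelled descriptor panel with random sparse intensities
random_panel <- function(n_per_class = 10, n_features = 12,
                         density = 0.4) {
  x <- matrix(rexp(2 * n_per_class * n_features) *
                (runif(2 * n_per_class * n_features) < density),
              nrow = 2 * n_per_class)
  colnames(x) <- feature_label(seq_len(n_features))
  labels <- factor(rep(c("agonist", "non-agonist"), each = n_per_class))
  list(x = x, labels = labels)
}

# receptor_structure built directly in memory (no file round trip)
make_receptor <- function(residue_name, residue_number, atom_name, element,
                          xyz, chain = "A") {
  structure(list(atoms = data.frame(residue_name = residue_name,
                                    residue_number = as.integer(residue_number),
                                    chain = chain, atom_name = atom_name,
                                    element = element,
                                    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                                    stringsAsFactors = FALSE),
                 source = "in-memory"),
            class = "receptor_structure")
}

make_pose <- function(element, xyz, ligand_id = "lig", pose_rank = 1L) {
  structure(list(ligand_id = ligand_id,
                 atoms = data.frame(element = element, x = xyz[, 1],
                                    y = xyz[, 2], z = xyz[, 3],
                                    stringsAsFactors = FALSE),
                 pose_rank = pose_rank, properties = list()),
            class = "ligand_pose")
}

# fixed-column PDB ATOM line for hand-built receptor files
pdb_line <- function(serial, name, resid, chain, resno, x, y, z,
                     element = substr(name, 1, 1), alt = " ",
                     occupancy = 1.0, type = "ATOM  ") {
  name4 <- if (nchar(name) < 4) sprintf(" %-3s", name) else name
  sprintf("%s%5d %-4s%s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          type, serial, name4, alt, resid, chain, resno, x, y, z,
          occupancy, 0.0, element)
}

# three-residue receptor file used by the PDB parsing tests
write_tiny_pdb <- function(path) {
  writeLines(c(
    pdb_line(1, "N",  "GLY", "A", 10, 0.0, 0.0, 0.0),
    pdb_line(2, "CA", "GLY", "A", 10, 1.5, 0.0, 0.0, element = "C"),
    pdb_line(3, "N",  "ALA", "A", 11, 3.0, 0.0, 0.0),
    pdb_line(4, "CA", "ALA", "A", 11, 4.5, 0.0, 0.0, element = "C"),
    pdb_line(5, "N",  "TYR", "A", 12, 6.0, 0.0, 0.0),
    pdb_line(6, "OH", "TYR", "A", 12, 7.5, 0.0, 0.0, element = "O"),
    "END"), path)
  path
}

# uniform random rotation matrix (QR of a gaussian matrix, det +1)
random_rotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3))
  Q <- qr.Q(qr_)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}
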