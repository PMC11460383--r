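# Independent brute-force oracles and tiny text fixtures used across the
# suite.  The oracles deliberately share no code with the package kernels.

sinc <- function(x) ifelse(x == 0, 1, sin(x) / x)

# naive weighted pair histogram (ordered pairs; self mass separate)
naive_pc_hist <- function(xyz, w, dr, nbins) {
  bins <- numeric(nbins)
  n <- nrow(xyz)
  for (j in seq_len(n)) {
    for (k in seq_len(n)) {
      if (j == k) next
      r <- sqrt(sum((xyz[j, ] - xyz[k, ])^2))
      b <- min(round(r / dr), nbins - 1) + 1
      bins[b] <- bins[b] + w[j] * w[k]
    }
  }
  list(bins = bins, self_mass = sum(w^2))
}

# naive typed histogram: nbins x nt x nt ordered-pair counts
naive_typed_hist <- function(xyz, type, nt, dr, nbins) {
  cube <- array(0, dim = c(nbins, nt, nt))
  n <- nrow(xyz)
  d <- as.matrix(stats::dist(xyz))
  for (j in seq_len(n))
    for (k in seq_len(n)) {
      if (j == k) next
      b <- min(round(d[j, k] / dr), nbins - 1) + 1
      cube[b, type[j], type[k]] <- cube[b, type[j], type[k]] + 1
    }
  cube
}

# naive Debye double loop with per-atom form-factor values Aq (nq x n)
naive_debye <- function(xyz, Aq, q) {
  n <- nrow(xyz)
  i <- numeric(length(q))
  for (j in seq_len(n))
    for (k in seq_len(n)) {
      r <- sqrt(sum((xyz[j, ] - xyz[k, ])^2))
      i <- i + Aq[, j] * Aq[, k] * sinc(q * r)
    }
  i
}

model_xyz <- function(model) {
  as.matrix(model$atoms[, c("x", "y", "z")])
}

# per-atom form-factor value matrix for the naive Debye oracle
model_Aq <- function(model, q) {
  Am <- pddfsim:::type_ff_matrix(model$types, model$solvent_ed, q)
  Am[, model$atoms$type_index, drop = FALSE]
}

# relative L2 distance between two curves on a shared grid
rel_l2 <- function(a, b) sqrt(sum((a - b)^2) / sum(b^2))

# ---- text fixtures ----------------------------------------------------------

pdb_atom_line <- function(serial, name, resname, chain, resno, x, y, z,
                          occ = 1, b = 0, element = NULL, het = FALSE) {
  if (is.null(element)) element <- substr(trimws(name), 1, 1)
  nm <- if (nchar(name) < 4) paste0(" ", name) else name
  sprintf("%-6s%5d %-4s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          if (het) "HETATM" else "ATOM", serial, nm, " ", resname, chain,
          resno, x, y, z, occ, b, toupper(element))
}

# minimal tripeptide (ALA-GLY-SER backbone + side chains), one chain
write_mini_protein <- function(path) {
  l <- c(
    pdb_atom_line(1, "N",  "ALA", "A", 1, 0.000, 0.000, 0.000),
    pdb_atom_line(2, "CA", "ALA", "A", 1, 1.458, 0.000, 0.000),
    pdb_atom_line(3, "C",  "ALA", "A", 1, 2.009, 1.420, 0.000),
    pdb_atom_line(4, "O",  "ALA", "A", 1, 1.251, 2.390, 0.000),
    pdb_atom_line(5, "CB", "ALA", "A", 1, 1.988, -0.773, -1.199),
    pdb_atom_line(6, "N",  "GLY", "A", 2, 3.332, 1.536, 0.000),
    pdb_atom_line(7, "CA", "GLY", "A", 2, 3.988, 2.831, 0.000),
    pdb_atom_line(8, "C",  "GLY", "A", 2, 5.504, 2.705, 0.000),
    pdb_atom_line(9, "O",  "GLY", "A", 2, 6.062, 1.610, 0.000),
    pdb_atom_line(10, "N",  "SER", "B", 3, 6.189, 3.841, 0.000),
    pdb_atom_line(11, "CA", "SER", "B", 3, 7.644, 3.845, 0.000),
    pdb_atom_line(12, "C",  "SER", "B", 3, 8.212, 5.255, 0.000),
    pdb_atom_line(13, "O",  "SER", "B", 3, 7.476, 6.243, 0.000),
    pdb_atom_line(14, "CB", "SER", "B", 3, 8.174, 3.071, -1.212),
    pdb_atom_line(15, "OG", "SER", "B", 3, 7.743, 1.718, -1.214),
    pdb_atom_line(16, "O",  "HOH", "W", 101, 10.0, 10.0, 10.0, het = TRUE),
    pdb_atom_line(17, "MG", "MG",  "M", 201, -5.0, -5.0, -5.0,
                  element = "Mg", het = TRUE),
    "END")
  writeLines(l, path)
  path
}

write_altloc_pdb <- function(path) {
  a1 <- pdb_atom_line(1, "CA", "ALA", "A", 1, 0, 0, 0, occ = 0.6)
  a2 <- pdb_atom_line(2, "CA", "ALA", "A", 1, 1, 0, 0, occ = 0.4)
  # stamp altloc codes (column 17)
  substr(a1, 17, 17) <- "A"
  substr(a2, 17, 17) <- "B"
  writeLines(c(a1, a2,
               pdb_atom_line(3, "CB", "ALA", "A", 1, 0, 1.5, 0),
               "END"), path)
  path
}

write_multimodel_pdb <- function(path) {
  writeLines(c(
    "MODEL        1",
    pdb_atom_line(1, "CA", "GLY", "A", 1, 0, 0, 0),
    pdb_atom_line(2, "CA", "GLY", "A", 2, 3.8, 0, 0),
    "ENDMDL",
    "MODEL        2",
    pdb_atom_line(1, "CA", "GLY", "A", 1, 0, 0, 1),
    pdb_atom_line(2, "CA", "GLY", "A", 2, 5.8, 0, 1),
    "ENDMDL",
    "END"), path)
  path
}

write_biomt_pdb <- function(path) {
  writeLines(c(
    "REMARK 350 BIOMOLECULE: 1",
    "REMARK 350 APPLY THE FOLLOWING TO CHAINS: A",
    "REMARK 350   BIOMT1   1  1.000000  0.000000  0.000000        0.00000",
    "REMARK 350   BIOMT2   1  0.000000  1.000000  0.000000        0.00000",
    "REMARK 350   BIOMT3   1  0.000000  0.000000  1.000000        0.00000",
    "REMARK 350   BIOMT1   2 -1.000000  0.000000  0.000000       20.00000",
    "REMARK 350   BIOMT2   2  0.000000 -1.000000  0.000000        0.00000",
    "REMARK 350   BIOMT3   2  0.000000  0.000000  1.000000        0.00000",
    pdb_atom_line(1, "CA", "GLY", "A", 1, 1, 2, 3),
    pdb_atom_line(2, "CA", "GLY", "A", 2, 4, 2, 3),
    "END"), path)
  path
}

# two point-charge sites dz apart along z, as a typed structure model
two_point_model <- function(d = 5, dz = c(1, 1)) {
  point_model(rbind(c(0, 0, 0), c(0, 0, d)), dz = dz)
}

# paths where the deposited test structures would live; the files are not
# distributed with the package and must be fetched separately (see README)
pdb_fixture_path <- function(id) {
  testthat::test_path("pdb", paste0(id, ".pdb"))
}
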