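# Implicit-hydrogen counts for standard biopolymer residues: maps
# (residue name, atom name) to an atom-group label from the form-factor
# table.  Mid-chain protonation states are used throughout (amide NH,
# carboxylates ionized, Lys NH3, Arg guanidinium NH/NH2); termini are not
# special-cased, which matches the group-type treatment the typed
# histograms rely on.

aa_backbone <- c(N = "NH", CA = "CH", C = "C", O = "O", OXT = "O")

aa_sidechains <- list(
  ALA = c(CB = "CH3"),
  ARG = c(CB = "CH2", CG = "CH2", CD = "CH2", NE = "NH", CZ = "C",
          NH1 = "NH2", NH2 = "NH2"),
  ASN = c(CB = "CH2", CG = "C", OD1 = "O", ND2 = "NH2"),
  ASP = c(CB = "CH2", CG = "C", OD1 = "O", OD2 = "O"),
  CYS = c(CB = "CH2", SG = "SH"),
  GLN = c(CB = "CH2", CG = "CH2", CD = "C", OE1 = "O", NE2 = "NH2"),
  GLU = c(CB = "CH2", CG = "CH2", CD = "C", OE1 = "O", OE2 = "O"),
  GLY = character(0),
  HIS = c(CB = "CH2", CG = "C", ND1 = "N", CD2 = "CH", CE1 = "CH",
          NE2 = "NH"),
  ILE = c(CB = "CH", CG1 = "CH2", CG2 = "CH3", CD1 = "CH3", CD = "CH3"),
  LEU = c(CB = "CH2", CG = "CH", CD1 = "CH3", CD2 = "CH3"),
  LYS = c(CB = "CH2", CG = "CH2", CD = "CH2", CE = "CH2", NZ = "NH3"),
  MET = c(CB = "CH2", CG = "CH2", SD = "S", CE = "CH3"),
  PHE = c(CB = "CH2", CG = "C", CD1 = "CH", CD2 = "CH", CE1 = "CH",
          CE2 = "CH", CZ = "CH"),
  PRO = c(CB = "CH2", CG = "CH2", CD = "CH2"),
  SER = c(CB = "CH2", OG = "OH"),
  THR = c(CB = "CH", OG1 = "OH", CG2 = "CH3"),
  TRP = c(CB = "CH2", CG = "C", CD1 = "CH", CD2 = "C", NE1 = "NH",
          CE2 = "C", CE3 = "CH", CZ2 = "CH", CZ3 = "CH", CH2 = "CH"),
  TYR = c(CB = "CH2", CG = "C", CD1 = "CH", CD2 = "CH", CE1 = "CH",
          CE2 = "CH", CZ = "C", OH = "OH"),
  VAL = c(CB = "CH", CG1 = "CH3", CG2 = "CH3")
)

# nucleotide sugar-phosphate backbone; C2' is CH2 in DNA, CH + O2'(OH) in RNA
nt_backbone <- c(P = "P", OP1 = "O", OP2 = "O", O1P = "O", O2P = "O",
                 OP3 = "OH", O5p = "O", C5p = "CH2", C4p = "CH", O4p = "O",
                 C3p = "CH", O3p = "O", C1p = "CH", O2p = "OH")

nt_bases <- list(
  A = c(N9 = "N", C8 = "CH", N7 = "N", C5 = "C", C6 = "C", N6 = "NH2",
        N1 = "N", C2 = "CH", N3 = "N"),
  G = c(N9 = "N", C8 = "CH", N7 = "N", C5 = "C", C6 = "C", O6 = "O",
        N1 = "NH", C2 = "C", N2 = "NH2", N3 = "N"),
  C = c(N1 = "N", C2 = "C", O2 = "O", N3 = "N", C4 = "C", N4 = "NH2",
        C5 = "CH", C6 = "CH"),
  U = c(N1 = "N", C2 = "C", O2 = "O", N3 = "NH", C4 = "C", O4 = "O",
        C5 = "CH", C6 = "CH"),
  T = c(N1 = "N", C2 = "C", O2 = "O", N3 = "NH", C4 = "C", O4 = "O",
        C5 = "C", C6 = "CH", C7 = "CH3", C5M = "CH3")
)

nt_resnames <- c(A = "A", DA = "A", G = "G", DG = "G", C = "C", DC = "C",
                 U = "U", DU = "U", T = "T", DT = "T")

water_resnames <- c("HOH", "WAT", "H2O", "DOD", "TIP", "SOL")

# Returns the group label for one atom, or NA if the residue/atom is not in
# the dictionaries.
lookup_group_label <- function(resname, atom_name) {
  resname <- toupper(trimws(resname))
  an <- toupper(gsub("'", "p", trimws(atom_name)))
  if (resname %in% names(aa_sidechains)) {
    if (an %in% names(aa_backbone)) {
      lab <- aa_backbone[[an]]
      if (an == "CA" && resname == "GLY") lab <- "CH2"
      if (an == "N" && resname == "PRO") lab <- "N"
      return(lab)
    }
    sc <- aa_sidechains[[resname]]
    if (an %in% names(sc)) return(sc[[an]])
    return(NA_character_)
  }
  if (resname %in% names(nt_resnames)) {
    base <- nt_bases[[nt_resnames[[resname]]]]
    if (an %in% names(nt_backbone)) {
      lab <- nt_backbone[[an]]
      # DNA C2' carries two hydrogens (no O2')
      if (an == "C2p")
        lab <- if (startsWith(resname, "D")) "CH2" else "CH"
      return(lab)
    }
    if (an %in% names(base)) return(base[[an]])
    return(NA_character_)
  }
  if (resname %in% water_resnames) {
    if (startsWith(an, "O")) return("OH2")
    return(NA_character_)  # explicit water H: dropped (implicit in OH2)
  }
  NA_character_
}
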