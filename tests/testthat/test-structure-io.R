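test_that("a synthetic PDB parses to the expected scattering sites", {
  tf <- withr::local_tempfile(fileext = ".pdb")
  write_mini_protein(tf)
  suppressWarnings(m <- read_structure(tf))
  # 15 protein atoms; water and Mg excluded by default
  expect_equal(nrow(m$atoms), 15)
  expect_equal(m$atoms$x[2], 1.458)
  expect_equal(m$atoms$label[m$atoms$elety == "CB" &
                               m$atoms$resname == "ALA"], "CH3")
  expect_equal(m$atoms$label[m$atoms$elety == "N"][1], "NH")
  expect_equal(m$atoms$label[m$atoms$elety == "CA" &
                               m$atoms$resname == "GLY"], "CH2")
  expect_equal(m$atoms$label[m$atoms$elety == "OG"], "OH")

  suppressWarnings(mw <- read_structure(tf, include_waters = TRUE))
  expect_equal(nrow(mw$atoms), 16)
  expect_equal(mw$atoms$label[16], "OH2")
  suppressWarnings(mh <- read_structure(tf, include_het = TRUE,
                                        include_waters = TRUE))
  expect_equal(nrow(mh$atoms), 17)
  expect_true("Mg" %in% mh$atoms$label)
})

test_that("the same structure parses identically from mmCIF", {
  tf <- withr::local_tempfile(fileext = ".cif")
  hdr <- c("data_fix", "loop_",
           paste0("_atom_site.",
                  c("group_PDB", "id", "type_symbol", "label_atom_id",
                    "label_alt_id", "label_comp_id", "label_asym_id",
                    "label_entity_id", "label_seq_id", "pdbx_PDB_ins_code",
                    "Cartn_x", "Cartn_y", "Cartn_z", "occupancy",
                    "B_iso_or_equiv", "pdbx_formal_charge", "auth_seq_id",
                    "auth_comp_id", "auth_asym_id", "auth_atom_id",
                    "pdbx_PDB_model_num")))
  row <- function(id, el, nm, res, seq, x, y, z)
    sprintf("ATOM %d %s %s . %s A 1 %d ? %.3f %.3f %.3f 1.00 0.00 ? %d %s A %s 1",
            id, el, nm, res, seq, x, y, z, seq, res, nm)
  writeLines(c(hdr,
               row(1, "N", "N", "ALA", 1, 0, 0, 0),
               row(2, "C", "CA", "ALA", 1, 1.458, 0, 0),
               row(3, "C", "CB", "ALA", 1, 2.0, 1.4, 0)), tf)
  m <- read_structure(tf)
  expect_equal(nrow(m$atoms), 3)
  expect_equal(m$atoms$label, c("NH", "CH", "CH3"))
  expect_equal(m$atoms$x, c(0, 1.458, 2.0))
})

test_that("alternate locations resolve to the highest occupancy", {
  tf <- withr::local_tempfile(fileext = ".pdb")
  write_altloc_pdb(tf)
  m <- read_structure(tf)
  expect_equal(nrow(m$atoms), 2)
  ca <- m$atoms[m$atoms$elety == "CA", ]
  expect_equal(ca$x, 0)  # conformer A, occupancy 0.6
})

test_that("NMR-style multi-model files honour the model argument", {
  tf <- withr::local_tempfile(fileext = ".pdb")
  write_multimodel_pdb(tf)
  m1 <- read_structure(tf, model = 1)
  m2 <- read_structure(tf, model = 2)
  expect_equal(max_pair_distance(m1), 3.8)
  expect_equal(max_pair_distance(m2), 5.8)
  expect_error(read_structure(tf, model = 3), "model")
})

test_that("biological-assembly expansion applies BIOMT transforms", {
  tf <- withr::local_tempfile(fileext = ".pdb")
  write_biomt_pdb(tf)
  m0 <- read_structure(tf)
  m1 <- read_structure(tf, assembly = TRUE)
  expect_equal(nrow(m1$atoms), 2 * nrow(m0$atoms))
  # second copy: (x, y) -> (20 - x, -y)
  expect_equal(sort(m1$atoms$x), sort(c(1, 4, 19, 16)))
})

test_that("atom typing keeps N_T in the biomolecular range and is stable", {
  # protein-ish fixture with all common groups
  labs <- c("C", "CH", "CH2", "CH3", "N", "NH", "NH2", "NH3", "O", "OH",
            "S", "SH")
  n <- length(labs)
  m <- structure_model(data.frame(x = seq_len(n) * 2, y = 0, z = 0,
                                  label = labs))
  m <- assign_atom_types(m)
  expect_gte(n_types(m), 10)
  expect_lte(n_types(m), 15)
  # deterministic and order-independent
  perm <- sample(n)
  m2 <- assign_atom_types(structure_model(
    data.frame(x = seq_len(n), y = 0, z = 0, label = labs[perm])))
  expect_setequal(m2$types$label, m$types$label)
  expect_equal(m2$atoms$z_el, m$atoms$z_el[perm])
})

test_that("effective electrons follow dz = Z - rho V", {
  fx <- make_fixture("sphere", n = 30, radius = 8, seed = 2,
                     solvent_ed = 0)
  expect_equal(effective_electrons(fx$model), rep(6, 30))
  # stated arithmetic: Z = 8, V = 30, rho = 0.334 -> -2.02
  m <- structure_model(data.frame(x = 0, y = 0, z = 0, label = "OH2"),
                       solvent_ed = 0.334)
  m <- assign_atom_types(m)
  expect_equal(effective_electrons(m), 10 - 0.334 * 30, tolerance = 1e-12)
  # cross-module identity: sum(dz)^2 = I(0) from the Debye engine
  fx <- make_fixture("sphere", n = 40, radius = 9, seed = 5,
                     solvent_ed = 0.334)
  expect_equal(dd_xs(fx$model, 0)$i,
               sum(effective_electrons(fx$model))^2, tolerance = 1e-12)
})

test_that("max pair distance equals the brute-force maximum", {
  m <- two_point_model(d = 5)
  expect_equal(max_pair_distance(m), 5)
  set.seed(31)
  xyz <- matrix(rnorm(600, sd = 10), ncol = 3)
  pm <- point_model(xyz)
  expect_equal(max_pair_distance(pm), max(stats::dist(xyz)))
  expect_error(max_pair_distance(point_model(matrix(0, 1, 3))), "2 atoms")
})

test_that("site TSV round-trips the model exactly", {
  fx <- make_fixture("ring", seed = 3, solvent_ed = 0.334)
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_sites_tsv(fx$model, tf)
  m2 <- read_sites_tsv(tf)
  expect_identical(m2$atoms$x, fx$model$atoms$x)
  expect_identical(m2$atoms$label, fx$model$atoms$label)
  expect_identical(m2$atoms$chain, fx$model$atoms$chain)
  expect_equal(m2$solvent_ed, 0.334)
  expect_equal(effective_electrons(m2), effective_electrons(fx$model))
})

test_that("fixture PDB files re-read to the identical model", {
  tf <- withr::local_tempfile(fileext = ".pdb")
  fx <- make_fixture("helix", n = 12, seed = 1, path = tf)
  m2 <- read_structure(tf, solvent_ed = 0)
  expect_equal(m2$atoms$x, fx$model$atoms$x)
  expect_equal(m2$atoms$y, fx$model$atoms$y)
  expect_equal(m2$atoms$z, fx$model$atoms$z)
  expect_equal(m2$atoms$label, fx$model$atoms$label)
})

test_that("the selection mini-language selects what it says", {
  tf <- withr::local_tempfile(fileext = ".pdb")
  write_mini_protein(tf)
  suppressWarnings(m <- read_structure(tf, include_het = TRUE,
                                       include_waters = TRUE))
  expect_equal(length(select_atoms(m, "chain A")), 9)
  expect_equal(length(select_atoms(m, "chains A,B")), 15)
  expect_equal(length(select_atoms(m, "resname MG")), 1)
  expect_equal(length(select_atoms(m, "resi 1-2")), 9)
  expect_equal(select_atoms(m, "chain B and resname SER"),
               select_atoms(m, "resi 3"))
  expect_equal(select_atoms(m, c(2, 4, 6)), c(2L, 4L, 6L))
  expect_error(parse_selection("frobnicate Z"), "keyword")
})

test_that("unknown residues fall back to element typing with a warning", {
  tf <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(pdb_atom_line(1, "C1", "LIG", "A", 1, 0, 0, 0, het = TRUE),
               pdb_atom_line(2, "O1", "LIG", "A", 1, 1.4, 0, 0, het = TRUE),
               "END"), tf)
  expect_warning(m <- read_structure(tf, include_het = TRUE),
                 "element-only")
  expect_equal(m$atoms$label, c("C", "O"))
})
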