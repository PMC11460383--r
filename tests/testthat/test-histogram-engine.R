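test_that("three collinear atoms bin exactly as enumerated", {
  m <- point_model(rbind(c(0, 0, 0), c(0, 0, 3), c(0, 0, 6)), dz = 1)
  h <- build_histograms(m, dr = 1)
  expect_equal(sum(h$self_counts), 3)
  hh <- h$counts[, 1, 1]
  expect_equal(hh[4], 4)  # two pairs at 3 A, ordered
  expect_equal(hh[7], 2)  # one pair at 6 A, ordered
  expect_equal(sum(hh) + sum(h$self_counts), 9)  # N_A^2
})

test_that("ordered-pair counts always total N_A^2 and stay symmetric", {
  fx <- make_fixture("ring", n_subunits = 5, subunit_n = 8, seed = 12)
  m <- fx$model
  m$atoms$label <- rep(c("C", "N", "O"), length.out = nrow(m$atoms))
  m <- assign_atom_types(m)
  h <- build_histograms(m, dr = 0.3)
  n <- nrow(m$atoms)
  expect_equal(sum(h$counts) + sum(h$self_counts), n^2)
  for (s in 1:3) for (t in 1:3)
    expect_equal(h$counts[, s, t], h$counts[, t, s])
})

test_that("typed histograms equal a naive loop bin-exactly", {
  fx <- make_fixture("sphere", n = 1000, radius = 18, seed = 19)
  m <- fx$model
  m$atoms$label <- rep(c("C", "NH"), length.out = 1000)
  m <- assign_atom_types(m)
  h <- build_histograms(m, dr = 0.4)
  ref <- naive_typed_hist(model_xyz(m), m$atoms$type_index, 2, 0.4,
                          dim(h$counts)[1])
  expect_identical(unname(h$counts), unname(ref))
})

test_that("DH engines converge to the direct engines in the fine-bin limit", {
  # commensurate geometry: a 20-site linear stack, pair distances exact
  # multiples of the rise, so dr = 1e-4 bins centre every distance exactly
  fx <- make_fixture("ladder", n_rungs = 20, rise = 3.4, width = 0,
                     seed = 1, solvent_ed = 0.334)
  m <- fx$model
  m$atoms$label <- rep(c("C", "N"), length.out = 20)  # exercise typed paths
  m <- assign_atom_types(m)
  q <- default_q_grid()
  h <- build_histograms(m, dr = 1e-4)
  expect_lt(max(abs(dh_xs(h, q)$i - dd_xs(m, q)$i) / abs(dd_xs(m, q)$i)),
            1e-8)
  p_dh <- dh_pddf(h, dr = 0.5)
  p_dd <- dd_pddf(m, dr = 0.5, r_max = max(p_dh$r))
  expect_lt(rel_l2(p_dh$p, p_dd$p), 1e-6)
})

test_that("binning error decays with the histogram bin width", {
  fx <- make_fixture("sphere", n = 20, radius = 8, seed = 5)
  q <- default_q_grid()
  idd <- dd_xs(fx$model, q)$i
  errs <- vapply(c(1e-2, 1e-3, 1e-4), function(drh) {
    max(abs(dh_xs(build_histograms(fx$model, drh), q)$i - idd) / abs(idd))
  }, 0)
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[3], 1e-4)
})

test_that("forward scattering from histograms is exact at any bin width", {
  fx <- make_fixture("sphere", n = 150, radius = 12, seed = 3,
                     solvent_ed = 0.334)
  dz <- effective_electrons(fx$model)
  for (drh in c(1.5, 0.5, 0.2)) {
    h <- build_histograms(fx$model, dr = drh)
    expect_equal(dh_xs(h, 0)$i, sum(dz)^2, tolerance = 1e-12)
    expect_equal(pddf_area(dh_pddf(h, dr = 0.5)), sum(dz)^2,
                 tolerance = 1e-9)
  }
})

test_that("a globular fixture reproduces direct-Debye accuracy bands", {
  fx <- make_fixture("sphere", n = 600, radius = 15.5,
                     axes = c(0.85, 1, 1.3), seed = 42)
  m <- fx$model
  q <- default_q_grid()
  ix <- dd_xs(m, q)
  h <- build_histograms(m, dr = 0.2)
  ih <- dh_xs(h, q)
  rel <- abs(ih$i - ix$i) / abs(ix$i)
  expect_lt(max(rel[q < 0.2]), 0.001)
  expect_lt(max(rel[q >= 0.2]), 0.02)
  p_dd <- dd_pddf(m, dr = 0.5)
  p_dh <- dh_pddf(h, dr = 0.5, r_max = max(p_dd$r))
  dmax <- fx$info$dmax
  sel <- p_dd$r > 0.05 * dmax & p_dd$r < 0.9 * dmax
  expect_lt(max(abs(p_dh$p - p_dd$p)[sel]) / max(abs(p_dd$p)), 0.01)
})

test_that("histogram cache files round-trip", {
  fx <- make_fixture("helix", n = 30, seed = 7, solvent_ed = 0.334)
  m <- fx$model
  m$atoms$label <- rep(c("C", "O"), length.out = 30)
  m <- assign_atom_types(m)
  h <- build_histograms(m, dr = 0.25)
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_histograms(h, tf)
  h2 <- read_histograms(tf)
  expect_equal(h2$labels, h$labels)
  expect_equal(unname(h2$counts), unname(h$counts))
  expect_equal(h2$self_counts, h$self_counts)
  q <- seq(0, 2, length.out = 40)
  expect_equal(dh_xs(h2, q)$i, dh_xs(h, q)$i, tolerance = 1e-12)
})

test_that("dh errors cleanly on bad inputs", {
  fx <- make_fixture("two_atom")
  expect_error(build_histograms(fx$model, dr = 0), "dr")
  h <- build_histograms(fx$model, dr = 0.2)
  expect_error(dh_xs(h, c(-1, 0)), "negative")
})
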