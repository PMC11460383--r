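test_that("a two-site dimer decomposes by enumeration", {
  m <- two_point_model(d = 5, dz = c(1, 1))
  dec <- decompose_pddf(m, subunits = list(A = 1, B = 2), method = "PC",
                        dr = 0.5)
  expect_equal(dec$subunit$A$self_mass, 1)
  expect_equal(dec$subunit$B$self_mass, 1)
  expect_true(all(dec$subunit$A$p == 0))
  corr <- dec$correlation[["A|B"]]
  b5 <- which.min(abs(corr$r - 5))
  expect_equal(corr$p[b5] * corr$dr, 2)
  expect_equal(sum(corr$p) * corr$dr, 2)
  whole <- pc_pddf(m, dr = 0.5, r_max = max(corr$r))
  expect_equal(dec$total$p, whole$p)
  expect_lt(dec$residual, 1e-12)
})

test_that("correlation support is bounded by the cross-distance range", {
  a <- make_fixture("sphere", n = 25, radius = 4, seed = 2)$model
  b <- make_fixture("sphere", n = 25, radius = 4, seed = 3)$model
  b$atoms$z <- b$atoms$z + 30
  b$atoms$chain <- "B"
  m <- combine_models(a, b)
  xyz_a <- model_xyz(a); xyz_b <- model_xyz(b)
  cross <- sqrt(outer(rowSums(xyz_a^2), rowSums(xyz_b^2), `+`) -
                  2 * xyz_a %*% t(xyz_b))
  # PC: support exact to the bin rule; DH: the analytic Gaussian kernel
  # broadens each histogram bin by its (finite) width
  for (meth in c("PC", "DH")) {
    dec <- decompose_pddf(m, subunits = list(A = "chain A", B = "chain B"),
                          method = meth, dr = 0.5, dr_hist = 0.1)
    corr <- dec$correlation[["A|B"]]
    thr <- if (meth == "PC") 0 else 1e-6 * max(abs(corr$p))
    nz <- corr$r[abs(corr$p) > thr]
    pad <- if (meth == "PC") 0.5 else 8
    expect_gte(min(nz), min(cross) - pad)
    expect_lte(max(nz), max(cross) + pad)
  }
})

test_that("an eight-subunit ring decomposes additively for all engines", {
  fx <- make_fixture("ring", seed = 9, solvent_ed = 0.334)
  m <- fx$model
  for (meth in c("PC", "DH", "DD")) {
    dec <- decompose_pddf(m, method = meth, dr = 0.25, dr_hist = 0.05)
    expect_length(dec$subunit, 8)
    expect_length(dec$correlation, 8 * 7 / 2)
    expect_lt(dec$residual, 1e-9)
  }
  # short distances arise from the internal structure of the subunits;
  # the nearest-neighbour correlation peaks near the ring chord distance
  dec <- decompose_pddf(m, method = "PC", dr = 0.25)
  intra <- Reduce(`+`, lapply(dec$subunit, `[[`, "p"))
  corr_all <- Reduce(`+`, lapply(dec$correlation, `[[`, "p"))
  small_r <- dec$total$r < 3 & dec$total$r > 0
  expect_gt(sum(intra[small_r]), 5 * sum(abs(corr_all[small_r])))
  corr_nn <- dec$correlation[["A|B"]]
  peak_r <- corr_nn$r[which.max(corr_nn$p)]
  expect_lt(abs(peak_r - fx$info$chord), 1.5)
})

test_that("subunit order does not change the decomposition", {
  fx <- make_fixture("ring", n_subunits = 4, subunit_n = 6, seed = 5)
  m <- fx$model
  d1 <- decompose_pddf(m, subunits = list(A = "chain A", B = "chain B",
                                          C = "chain C", D = "chain D"),
                       method = "PC", dr = 0.5)
  d2 <- decompose_pddf(m, subunits = list(D = "chain D", B = "chain B",
                                          A = "chain A", C = "chain C"),
                       method = "PC", dr = 0.5)
  expect_equal(d1$total$p, d2$total$p)
  expect_equal(d1$subunit$A$p, d2$subunit$A$p)
  expect_equal(d1$correlation[["A|B"]], d2$correlation[["B|A"]],
               ignore_attr = TRUE)
})

test_that("overlapping or incomplete selections are refused", {
  fx <- make_fixture("ring", n_subunits = 3, subunit_n = 4, seed = 2)
  expect_error(decompose_pddf(fx$model,
                              subunits = list(A = "chain A",
                                              AB = "chains A,B",
                                              C = "chain C"),
                              method = "PC"),
               "overlap")
  expect_error(decompose_pddf(fx$model,
                              subunits = list(A = "chain A", B = "chain B"),
                              method = "PC"),
               "cover")
})
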