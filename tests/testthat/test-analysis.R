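test_that("a rectangular PDDF has apparent = true Dmax at any threshold", {
  r <- seq(0, 15, by = 0.5)
  p <- pddf_curve(r, ifelse(r <= 10, 1, 0), method = "PC")
  for (thr in c(0.5, 0.01, 0.001)) {
    rep_ <- apparent_dmax(p, true_dmax = 10, threshold = thr)
    expect_equal(rep_$apparent_dmax, 10)
    expect_equal(rep_$gap, 0)
  }
  expect_error(apparent_dmax(p, 10, threshold = 0), "threshold")
  expect_error(apparent_dmax(pddf_curve(r, numeric(length(r))), 10),
               "all-zero")
})

test_that("raising the threshold never increases the apparent Dmax", {
  fx <- make_fixture("sphere", n = 250, radius = 14, seed = 21,
                     solvent_ed = 0.334)
  p <- dh_pddf(build_histograms(fx$model, 0.2), dr = 0.5)
  true_d <- fx$info$dmax
  thr <- c(1e-4, 1e-3, 1e-2, 0.1)
  app <- vapply(thr, function(t)
    apparent_dmax(p, true_d, threshold = t)$apparent_dmax, 0)
  expect_true(all(diff(app) <= 0))
  rep1 <- apparent_dmax(p, true_d)
  expect_lte(rep1$apparent_dmax, rep1$true_dmax)
  expect_gte(rep1$gap, 0)
  # threshold -> 0 recovers the support of the stored curve
  tiny <- apparent_dmax(p, true_d, threshold = 1e-12)
  expect_equal(tiny$apparent_dmax,
               min(max(p$r[p$p > 0]), true_d))
})

test_that("reports serialize to JSON with the documented fields", {
  fx <- make_fixture("helix", n = 15, seed = 4)
  p <- pc_pddf(fx$model)
  rep_ <- apparent_dmax(p, fx$info$dmax)
  tf <- withr::local_tempfile(fileext = ".json")
  dmax_report_json(rep_, tf)
  j <- jsonlite::fromJSON(tf)
  expect_setequal(names(j), c("true_dmax", "apparent_dmax", "threshold",
                              "gap", "method", "dr"))
  expect_equal(j$gap, rep_$gap)
})

test_that("normalization modes scale as documented", {
  fx <- make_fixture("sphere", n = 50, radius = 9, seed = 15)
  p <- pc_pddf(fx$model)
  expect_identical(normalize_pddf(p, "per_particle"), p)
  mw <- molecular_weight(fx$model)
  expect_equal(mw, 50 * 12.011 / 1000, tolerance = 1e-4)
  pm <- normalize_pddf(p, "per_mass", mw = mw)
  expect_equal(pm$p, p$p / mw)
  expect_equal(pm$self_mass, p$self_mass / mw)
  expect_error(normalize_pddf(p, "per_mass"), "mw")
  # a 2x heavier assembly halves relative to per-particle comparison
  p2 <- normalize_pddf(p, "per_mass", mw = 2 * mw)
  expect_equal(p2$p, pm$p / 2)
})

test_that("guest insertion shifts the PDDF area independently of position", {
  shell <- make_fixture("shell", n = 400, radius = 30, thickness = 6,
                        seed = 31)$model
  guest_c <- make_fixture("sphere", n = 60, radius = 6, seed = 32)$model
  guest_off <- guest_c
  guest_off$atoms$x <- guest_off$atoms$x + 18  # near the wall
  r_max <- 80
  area <- function(m) pddf_area(pc_pddf(m, dr = 0.5, r_max = r_max))
  a_shell <- area(shell)
  a_c <- area(combine_models(shell, guest_c))
  a_off <- area(combine_models(shell, guest_off))
  dz_s <- sum(effective_electrons(shell))
  dz_g <- sum(effective_electrons(guest_c))
  expected <- dz_g^2 + 2 * dz_g * dz_s
  expect_equal(a_c - a_shell, expected, tolerance = 1e-9)
  expect_equal(a_off - a_shell, expected, tolerance = 1e-9)
  expect_equal(a_c, a_off, tolerance = 1e-9)
})

test_that("shell fixtures look like hollow particles", {
  fx <- make_fixture("shell", n = 800, radius = 30, thickness = 6, seed = 8)
  expect_gte(fx$info$dmax, 2 * (30 - 3))
  expect_lte(fx$info$dmax, 2 * (30 + 3) + 0.01)
  p <- pc_pddf(fx$model, dr = 0.5)
  # hollow particle: PDDF peak beyond the radius (sphere peaks near
  # ~ 1.05 R for a solid ball of the same outer radius)
  expect_gt(p$r[which.max(p$p)], 30)
})
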