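test_that("single- and two-atom Debye sums match closed forms", {
  q <- default_q_grid()
  one <- subset_model(make_fixture("two_atom", d = 5)$model, 1)
  A <- evaluate_gaussian_sum(combined_form_factor("C", 0), q)
  expect_equal(dd_xs(one, q)$i, A^2, tolerance = 1e-14)
  m <- make_fixture("two_atom", d = 5)$model
  expect_equal(dd_xs(m, q)$i, 2 * A^2 * (1 + sinc(q * 5)), tolerance = 1e-12)
})

test_that("dd_xs equals an independent naive double loop", {
  fx <- make_fixture("sphere", n = 50, radius = 9, seed = 23,
                     solvent_ed = 0.334)
  q <- seq(0, 3, length.out = 60)
  i_ref <- naive_debye(model_xyz(fx$model), model_Aq(fx$model, q), q)
  expect_equal(dd_xs(fx$model, q)$i, i_ref, tolerance = 1e-12)
})

test_that("one Gaussian pair term matches direct numerical quadrature", {
  # a single pair at distance a with a single-term product c e^{-d q^2}:
  # bin masses of the analytic kernel vs a double numerical integral of
  # the inverse transform (independent of the erf closed form)
  a <- 6.0; d <- 0.4; cc <- 2.5; dr <- 0.25
  nr <- 49L  # bins centred on m * dr, m = 0..48
  centres <- (seq_len(nr) - 1) * dr
  edges_lo <- pmax(0, centres - dr / 2)
  edges_hi <- centres + dr / 2
  q <- seq(0, 40, by = 5e-4)
  dq <- q[2] - q[1]
  iq <- cc * exp(-d * q^2) * sinc(q * a)
  prim <- function(e) {  # closed-form of the exact r-integral over a bin
    out <- (sin(q * e) - q * e * cos(q * e)) / q^2
    out[q == 0] <- 0
    out
  }
  mass_num <- vapply(seq_len(nr), function(m) {
    (2 / pi) * sum(q * iq * (prim(edges_hi[m]) - prim(edges_lo[m]))) * dq
  }, 0)
  mass_pkg <- numeric(nr)
  pddfsim:::cpp_accum_gauss_bins(mass_pkg, a, cc, d, dr, FALSE)
  expect_lt(sqrt(sum((mass_pkg - mass_num)^2) / sum(mass_num^2)), 1e-6)
  # peak located within dr of the pair distance
  expect_lt(abs(centres[which.max(mass_pkg)] - a), dr + 1e-12)
})

test_that("the analytic PDDF collapses to the point-charge limit", {
  set.seed(41)
  xyz <- matrix(rnorm(90, sd = 6), ncol = 3)
  m <- point_model(xyz, dz = c(1, 2, 0.5))
  p_dd <- dd_pddf(m, dr = 0.2)
  p_pc <- pc_pddf(m, dr = 0.2, r_max = max(p_dd$r))
  # constant form factors have d = 0 terms: pure histogram binning, with
  # the self mass appearing in the r = 0 bin instead of separately
  mass_dd <- p_dd$p * pddfsim:::bin_widths(length(p_dd$r), p_dd$dr)
  mass_pc <- p_pc$p * pddfsim:::bin_widths(length(p_pc$r), p_pc$dr)
  mass_pc[1] <- mass_pc[1] + p_pc$self_mass
  expect_equal(mass_dd, mass_pc, tolerance = 1e-9)
})

test_that("whole-model analytic PDDF area equals the forward scattering", {
  for (rho in c(0, 0.334)) {
    fx <- make_fixture("helix", n = 25, seed = 6, solvent_ed = rho)
    p <- dd_pddf(fx$model, dr = 0.5)
    i0 <- dd_xs(fx$model, 0)$i
    expect_equal(pddf_area(p), i0, tolerance = 5e-3)
    expect_lt(abs(pddf_area(p) - i0) / i0, 1e-9)
  }
})

test_that("numerical inverse FT inverts sinc kernels and the Debye PDDF", {
  q <- seq(0, 30, by = 0.01)
  xs <- xs_curve(q, 3 * sinc(q * 7))
  p <- xs_to_pddf_numeric(xs, seq(0, 15, by = 0.1))
  expect_lt(abs(p$r[which.max(p$p)] - 7), 0.1 + 1e-9)
  expect_equal(sum(p$p * pddfsim:::bin_widths(length(p$r), 0.1)), 3,
               tolerance = 1e-3)

  fx <- make_fixture("sphere", n = 10, radius = 8, seed = 3)
  qd <- seq(0, 50, by = 0.001)
  ix <- dd_xs(fx$model, qd)
  rg <- seq(0, 25, by = 0.05)
  p_num <- xs_to_pddf_numeric(ix, rg)
  p_dd <- dd_pddf(fx$model, dr = 0.05, r_max = 25)
  expect_lt(rel_l2(p_num$p, p_dd$p), 1e-4)
})

test_that("truncating the transform at SAXS range warns and ripples", {
  fx <- make_fixture("sphere", n = 10, radius = 8, seed = 3)
  ix <- dd_xs(fx$model, seq(0, 3, length.out = 500))
  expect_warning(p <- xs_to_pddf_numeric(ix, seq(0, 30, by = 0.25)),
                 "truncated")
  # ripples: sign changes beyond the support of the true PDDF
  tail_p <- p$p[p$r > 18]
  expect_gt(sum(abs(diff(sign(tail_p[tail_p != 0]))) > 0), 2)
})

test_that("transform round trip reproduces the Debye intensity", {
  q <- default_q_grid()
  for (fx in list(make_fixture("two_atom", d = 5),
                  make_fixture("helix", n = 18, seed = 2,
                               solvent_ed = 0.334),
                  make_fixture("sphere", n = 60, radius = 10, seed = 8))) {
    ix <- dd_xs(fx$model, q)
    i_rt <- pddf_to_xs(dd_pddf(fx$model, dr = 0.05), q)
    expect_lt(max(abs(i_rt$i - ix$i) / abs(ix$i)), 5e-3)
  }
})

test_that("the Debye cost grows quadratically with atom count", {
  q <- seq(0, 3, length.out = 100)
  t_of <- function(n) {
    fx <- make_fixture("sphere", n = n, radius = n^(1 / 3) * 3, seed = 13)
    system.time(dd_xs(fx$model, q))[["elapsed"]]
  }
  t200 <- t_of(200)
  t800 <- t_of(800)
  expect_gt(t800 / max(t200, 1e-3), 4)  # ~16 for exact quadratic growth
})
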