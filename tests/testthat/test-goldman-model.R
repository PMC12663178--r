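test_that("derived constants match independent hand computation", {
  p <- goldman_params()
  cs <- derive_constants(p, k = 0.0046)
  expect_equal(cs$p0, 2e-5)                       # D/L with D = 1e-12, L = 50 nm
  # z e0 dPhi / kB T = 2 * 1.602176634e-19 * 0.125 / (1.380649e-23 * 300)
  expect_equal(cs$phi, 9.6704, tolerance = 1e-4)
  expect_equal(cs$alpha_m, exp(-cs$phi))
  # kappa from the cylinder geometry: 0.998239545 / 1.375e6 m
  expect_equal(cs$kappa, 7.2599e-7, tolerance = 1e-4)
  expect_equal(cs$theta, 0.0046 * 600)
  expect_equal(cs$alpha, cs$p0 * 600 * cs$phi / cs$kappa)
  # printed-value overrides are honored verbatim
  cs2 <- derive_constants(goldman_params(phi_override = 11.57,
                                         kappa_override = 8.68e5), 0.0046)
  expect_equal(cs2$phi, 11.57)
  expect_equal(cs2$kappa, 8.68e5)
})

test_that("permeability factorizes and decays with pore resealing", {
  law <- radial_law()
  k <- 0.0046; k1 <- 0.011
  # direct evaluation at gamma = 1, t = 0
  expect_equal(permeability_field(1, 0, k, k1, law), 0.0046 * 0.011 * 549)
  # ratio between t = 0 and t = 1/k is exactly e
  expect_equal(permeability_field(2, 0, k, k1, law) /
                 permeability_field(2, 1 / k, k, k1, law), exp(1))
  # vanishes at long times; strictly decreasing in t and gamma
  expect_lt(permeability_field(1, 1e7, k, k1, law), 1e-20)
  tgrid <- seq(0, 600, 50)
  pg <- permeability_field(rep(1, length(tgrid)), tgrid, k, k1, law)
  expect_true(all(diff(pg) < 0))
  gg <- seq(0.2, 3, 0.2)
  expect_true(all(diff(permeability_field(gg, 0, k, k1, law)) < 0))
  # exact separability P(gamma, t) = f(gamma) g(t)
  P <- outer(gg, tgrid, function(g, t) permeability_field(g, t, k, k1, law))
  expect_equal(P, outer(permeability_field(gg, 0, k, k1, law),
                        exp(-k * tgrid)))
  expect_error(permeability_field(-1, 0, k, k1, law), "positive")
})

test_that("damage fraction is normalized to total damage at 2500 AU", {
  k <- 0.0046; k1 <- 0.011
  # a cell whose plateau is exactly I_100 at t = 0 is 100% damaged
  law100 <- radial_law(2500, 0)
  expect_equal(damage_fraction(1, 0, k, k1, law100), 1)
  # brighter cells cap at 1; the raw expression is exposed uncapped
  law_hot <- radial_law(5000, 0)
  expect_equal(damage_fraction(1, 0, k, k1, law_hot), 1)
  expect_gt(damage_fraction(1, 0, k, k1, law_hot, normalize = FALSE), 1)
  # time decay is exp(-k t), independent of gamma
  law <- radial_law()
  for (g in c(0.3, 1, 2.5)) {
    expect_equal(damage_fraction(g, 100, k, k1, law) /
                   damage_fraction(g, 0, k, k1, law), exp(-k * 100))
  }
  expect_lt(damage_fraction(1, 1e6, k, k1, law), 1e-15)
})

test_that("the analytic Goldman solution satisfies its boundary behavior", {
  p <- goldman_params()
  cs <- derive_constants(p, 0.0046)
  # moderate flux scale so the solution is non-trivial on [0, 1]
  k1 <- cs$kappa / (cs$phi * 549)
  law <- radial_law()
  s0 <- solve_goldman_analytic(c(0.5, 1, 2), 0, cs, k1, law)
  expect_equal(s0$c1, rep(1, 3))
  expect_equal(s0$c2, rep(0, 3))
  # long-time limit exp(-(phi k1 / kappa) I_final)
  sInf <- solve_goldman_analytic(1, 1e9, cs, k1, law)
  expect_equal(sInf$c1, exp(-(cs$phi * k1 / cs$kappa) * 549))
  # c2 nondecreasing in t for random parameter draws
  set.seed(8)
  for (i in 1:10) {
    csr <- derive_constants(goldman_params(), k = runif(1, 0.001, 0.01))
    k1r <- csr$kappa / (csr$phi * runif(1, 100, 3000))
    g <- runif(1, 0.1, 3)
    c2 <- solve_goldman_analytic(rep(g, 50), seq(0, 1, length.out = 50),
                                 csr, k1r)$c2
    expect_true(all(diff(c2) >= -1e-12))
    expect_true(all(c2 >= 0 & c2 <= 1))
  }
})

test_that("numeric integration matches the closed form when alpha_m -> 0", {
  p <- goldman_params()
  cs <- derive_constants(p, 0.0046)
  k1 <- cs$kappa / (cs$phi * 400)     # exponent O(1) over the gamma range
  p1 <- goldman_params(k1 = k1)
  gamma <- seq(0.2, 3, length.out = 12)
  td <- seq(0, 1, length.out = 25)
  num <- solve_goldman_numeric(p1, 0.0046, gamma, td, alpha_m = 0)
  ana <- solve_goldman_analytic(rep(gamma, each = length(td)),
                                rep(td, length(gamma)), cs, k1)
  expect_equal(as.vector(t(num$c1)), ana$c1, tolerance = 1e-7)
  # conservation holds to solver tolerance
  expect_lt(max(abs(num$c1 + num$c2 - 1)), 1e-8)
  # with full alpha_m the correction is tiny but c1 stays a proper fraction
  num2 <- solve_goldman_numeric(p1, 0.0046, c(1), td)
  expect_true(all(num2$c1 >= 0 & num2$c1 <= 1))
  # zero permeability (alpha = 0 via k1 -> 0) leaves c1 at 1
  num3 <- solve_goldman_numeric(goldman_params(k1 = 1e-300), 0.0046, 1, td)
  expect_equal(as.vector(num3$c1), rep(1, length(td)), tolerance = 1e-10)
  expect_error(solve_goldman_numeric(p1, 0.0046, numeric(), td), "empty")
})

test_that("the literal two-equation system reports its continuity coupling", {
  # with beta = 1/2 the printed coupling (beta-1)/beta = -1 conserves dye
  p <- goldman_params(beta = 0.5)
  cs <- derive_constants(p, 0.0046)
  k1 <- cs$kappa / (cs$phi * 400)
  p <- goldman_params(beta = 0.5, k1 = k1)
  td <- seq(0, 1, length.out = 11)
  sol <- solve_goldman_numeric(p, 0.0046, 1, td, conserve = FALSE)
  expect_lt(max(abs(sol$c1 + sol$c2 - 1)), 1e-7)
  # with beta = 0.41 it does not; the default solver is the conserving one
  p41 <- goldman_params(beta = 0.41, k1 = k1)
  sol41 <- solve_goldman_numeric(p41, 0.0046, 1, td, conserve = FALSE)
  expect_gt(max(abs(sol41$c1 + sol41$c2 - 1)), 1e-3)
})

test_that("linearized c2 stays within the Taylor remainder bound", {
  p <- goldman_params()
  cs <- derive_constants(p, 0.0046)
  law <- radial_law()
  for (x_target in c(0.01, 0.05, 0.099)) {
    k1 <- cs$kappa * x_target / (cs$phi * 549)   # exponent x_target at gamma = 1
    td <- seq(0, 1, length.out = 40)
    full <- solve_goldman_analytic(rep(1, 40), td, cs, k1, law)$c2
    lin <- c2_linearized(rep(1, 40), td, cs, k1, law)
    expect_lt(max(abs(lin - full)), x_target^2 / 2)
  }
  # shape identity: normalized linearized course is 1 - exp(-theta t)
  k1 <- cs$kappa * 0.01 / (cs$phi * 549)
  td <- seq(0, 1, length.out = 10)
  lin <- c2_linearized(rep(1, 10), td, cs, k1, law)
  lin_inf <- c2_linearized(1, 1e9, cs, k1, law)
  expect_equal(lin / lin_inf, 1 - exp(-cs$theta * td))
  expect_equal(c2_linearized(1, 0, cs, k1, law), 0)
  # validity warning above 0.1
  k1_big <- cs$kappa * 0.5 / (cs$phi * 549)
  expect_warning(c2_linearized(1, 0.5, cs, k1_big, law), "0.1")
})

test_that("k2 calibration and the potential relation are mutually inverse", {
  p <- goldman_params()
  cs <- derive_constants(p)
  k2 <- calibrate_k2(p, cs)
  expect_equal(k2 * cs$phi * p$k1 * p$c0 / cs$kappa, 1)
  # doubling c0 halves k2
  p2 <- goldman_params(c0 = 2 * p$c0)
  expect_equal(calibrate_k2(p2), k2 / 2)
  # round trip recovers the transmembrane potential to machine precision
  expect_equal(transmembrane_potential(p, p$k1, k2), p$dPhi_m)
  # potential inversely proportional to c0 and to valence
  expect_equal(transmembrane_potential(p2, p$k1, k2), p$dPhi_m / 2)
  pz <- goldman_params(z = 4)
  expect_equal(transmembrane_potential(pz, p$k1, calibrate_k2(p)),
               transmembrane_potential(goldman_params(z = 2), p$k1,
                                       calibrate_k2(p)) / 2)
})

test_that("field maps assemble consistent spatiotemporal surfaces", {
  p <- goldman_params()
  fm <- compute_field_map(p, k = 0.0046, gamma = c(0.5, 1, 2),
                          t_s = c(0, 300, 600))
  expect_identical(nrow(fm), 9L)
  expect_equal(fm$I[fm$t_s == 0], rep(0, 3))
  expect_equal(fm$c1[fm$t_s == 0], rep(1, 3))
  expect_true(all(fm$S_p >= 0 & fm$S_p <= 1))
  expect_lt(max(abs(fm$c1 + fm$c2 - 1)), 1e-8)
  # I increases toward the plateau; P/p0 decreases in time
  i1 <- fm$I[fm$gamma == 1]
  expect_true(all(diff(i1) > 0) && all(i1 < 549))
  expect_true(all(diff(fm$P_over_p0[fm$gamma == 1]) < 0))
  # numeric and analytic concentration routes agree at a moderate flux
  cs <- derive_constants(p, 0.0046)
  pm <- goldman_params(k1 = cs$kappa / (cs$phi * 400))
  fa <- compute_field_map(pm, 0.0046, gamma = c(0.5, 1), t_s = c(0, 300, 600))
  fn <- compute_field_map(pm, 0.0046, gamma = c(0.5, 1), t_s = c(0, 300, 600),
                          method = "numeric")
  # numeric retains the alpha_m ~ 6e-5 outward-flux correction
  expect_equal(fn$c1, fa$c1, tolerance = 1e-4)
  expect_error(compute_field_map(p, gamma = numeric()), "empty")
})
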