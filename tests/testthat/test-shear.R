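test_that("Kozeny-Carman permeability matches direct evaluation", {
  d <- areaToDiameter(0.0083e-12)
  expect_equal(d, 1.028e-7, tolerance = 1e-3)
  kp <- kozenyCarmanPermeability(0.2, 5.5, d)
  expect_equal(kp, 6.7e-19, tolerance = 0.01)
  # functional form: Kp ~ d^2 at fixed eps, K; halving K doubles Kp
  expect_equal(kozenyCarmanPermeability(0.2, 5.5, 2 * d), 4 * kp)
  expect_equal(kozenyCarmanPermeability(0.2, 2.75, d), 2 * kp)
  expect_error(kozenyCarmanPermeability(1, 5, d), "epsilon")
  expect_error(kozenyCarmanPermeability(0, 5, d), "epsilon")
})

test_that("Darcy shear stress matches direct evaluation and the chained example", {
  expect_equal(darcyShearStress(1e-3, 1e-6, 1e-18), 1.0)
  # linear in u
  expect_equal(darcyShearStress(1e-3, 3e-6, 1e-18), 3.0)
  # chained: mu 0.8 mPa s, u 0.4 um/s, Kp from (eps .2, K 4.5, area .18 um^2)
  kp <- kozenyCarmanPermeability(0.2, 4.5, areaToDiameter(0.18e-12))
  expect_equal(darcyShearStress(0.8e-3, 0.4e-6, kp), 0.076, tolerance = 0.01)
})

test_that("tau is monotone over the physical domain and dimensionally consistent", {
  base <- list(mu = 0.8e-3, u = 0.5e-6, eps = 0.2, K = 5, d = 2e-7)
  tau <- function(mu = base$mu, u = base$u, eps = base$eps, K = base$K,
                  d = base$d)
    darcyShearStress(mu, u, kozenyCarmanPermeability(eps, K, d))
  gr <- seq(0.5, 1.5, length.out = 7)
  expect_true(all(diff(tau(mu = base$mu * gr)) > 0))
  expect_true(all(diff(tau(u = base$u * gr)) > 0))
  expect_true(all(diff(tau(d = base$d * gr)) < 0))
  epsGrid <- seq(0.05, 0.5, length.out = 8)
  expect_true(all(diff(tau(eps = epsGrid)) < 0))
  # lengths x c: Kp x c^2, tau / c
  c0 <- 3.7
  expect_equal(kozenyCarmanPermeability(0.2, 5, c0 * base$d),
               c0^2 * kozenyCarmanPermeability(0.2, 5, base$d))
  expect_equal(tau(d = c0 * base$d), tau() / c0)
})

test_that("corner evaluation attains the same envelope as a dense grid", {
  cfg <- shearConfig(uUmPerS = c(0.4, 0.6), muMPaS = c(0.7, 1.0),
                     epsilon = c(0.15, 0.3), kozenyK = c(4.5, 5.5),
                     areaUm2 = c(0.0083, 0.18))
  est <- shearStressRange(cfg)
  grid <- expand.grid(u = seq(0.4, 0.6, length.out = 11),
                      mu = seq(0.7, 1.0, length.out = 11),
                      eps = seq(0.15, 0.3, length.out = 11),
                      K = seq(4.5, 5.5, length.out = 11),
                      a = seq(0.0083, 0.18, length.out = 11))
  tauG <- darcyShearStress(grid$mu * 1e-3, grid$u * 1e-6,
    kozenyCarmanPermeability(grid$eps, grid$K, areaToDiameter(grid$a * 1e-12)))
  expect_lte(tauRange(est)[1], min(tauG) + 1e-12)
  expect_gte(tauRange(est)[2], max(tauG) - 1e-12)
  expect_equal(tauRange(est)[1], min(tauG), tolerance = 1e-9)
  expect_equal(tauRange(est)[2], max(tauG), tolerance = 1e-9)
})

test_that("degenerate ranges collapse and widening a range widens the envelope", {
  pt <- shearConfig(uUmPerS = 0.5, muMPaS = 0.8, epsilon = 0.2,
                    kozenyK = 5, areaUm2 = 0.05)
  est <- shearStressRange(pt)
  expect_equal(tauRange(est)[1], tauRange(est)[2])
  wide <- shearStressRange(shearConfig(uUmPerS = c(0.3, 0.7)))
  narrow <- shearStressRange(shearConfig(uUmPerS = c(0.4, 0.6)))
  expect_lte(tauRange(wide)[1], tauRange(narrow)[1])
  expect_gte(tauRange(wide)[2], tauRange(narrow)[2])
  # attaining corners are reported
  expect_named(est@minCorner, c("uUmPerS", "muMPaS", "epsilon", "kozenyK",
                                "areaUm2"))
  # pluggable strategy functions are honoured
  est2 <- shearStressRange(pt, shearFun = function(mu, u, kp) 2 * mu * u / sqrt(kp))
  expect_equal(tauRange(est2)[1], 2 * tauRange(est)[1])
})
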