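# The volumetric gelation model: forward law, linearization, fitting.

test_that("capsule volumes follow the spherical formulas", {
  expect_equal(coreVolume(1000), (4 / 3) * pi * 1e9)
  expect_equal(shellVolume(700, 0), 0)
  expect_equal(shellVolume(500, 100), (4 / 3) * pi * (600^3 - 500^3))
  expect_gt(shellVolume(500, 1e-6), 0)  # V_s = 0 iff h = 0
  expect_error(coreVolume(0), class = "coreshell_domain")
  expect_error(shellVolume(500, -1), class = "coreshell_domain")
})

test_that("calcium load converts micrometre-millimolar units to moles", {
  # 1000 um radius core in 100 mM: V_c = 4/3 pi 1e9 um^3 = 4/3 pi 1e-6 L,
  # times 0.1 mol/L
  expect_equal(calciumMoles(100, 1000), (4 / 3) * pi * 1e-6 * 0.1)
  expect_equal(calciumMoles(0, 500), 0)  # n = 0 iff conc = 0
  expect_error(calciumMoles(-1, 500), class = "coreshell_domain")
})

test_that("predictThickness matches closed-form and oracle values", {
  expect_equal(predictThickness(shellModel(0.033), 0, 1000), 0)
  # perfect-cube argument: alpha*conc + 1 = 8, cube root 2
  expect_equal(predictThickness(0.05, 140, 500), 500)
  # independent oracle: root of (h/Rc + 1)^3 - 1 = alpha*conc
  oracle <- uniroot(function(h) (h / 1000 + 1)^3 - 1 - 0.033 * 100,
                    c(0, 2000), tol = 1e-12)$root
  expect_equal(predictThickness(0.033, 100, 1000), oracle,
               tolerance = 1e-9)
  expect_equal(round(oracle, 2), 626.13)
  expect_error(predictThickness(0.033, -1, 1000),
               class = "coreshell_domain")
  expect_error(predictThickness(0.033, 10, 0), class = "coreshell_domain")
  expect_error(predictThickness(-0.01, 10, 100),
               class = "coreshell_domain")
})

test_that("predicted thickness is strictly increasing in conc, alpha, Rc", {
  set.seed(42)
  for (i in 1:50) {
    a <- runif(1, 0.001, 0.5); cc <- runif(1, 0.1, 150)
    Rc <- runif(1, 50, 2000); eps <- 1e-6
    h0 <- predictThickness(a, cc, Rc)
    expect_gt(predictThickness(a, cc * (1 + eps), Rc), h0)
    expect_gt(predictThickness(a * (1 + eps), cc, Rc), h0)
    expect_gt(predictThickness(a, cc, Rc * (1 + eps)), h0)
  }
})

test_that("shell volume conserves the volumetric proportionality", {
  # V_s(Rc, h(conc)) = alpha * conc * V_c  (Eq. of the model, exactly)
  set.seed(7)
  for (i in 1:25) {
    a <- runif(1, 0.005, 0.2); cc <- runif(1, 0, 120)
    Rc <- runif(1, 100, 1500)
    h <- predictThickness(a, cc, Rc)
    expect_equal(shellVolume(Rc, h), a * cc * coreVolume(Rc),
                 tolerance = 1e-9)
  }
})

test_that("linearizedResponse inverts the forward law", {
  expect_equal(linearizedResponse(0, 700), 0)
  expect_equal(linearizedResponse(650, 650), 7)  # h = Rc: 2^3 - 1
  expect_error(linearizedResponse(-5, 700), class = "coreshell_domain")
  set.seed(13)
  for (i in 1:50) {
    a <- runif(1, 0.001, 0.5); cc <- runif(1, 0, 150)
    Rc <- runif(1, 50, 2000)
    expect_equal(linearizedResponse(predictThickness(a, cc, Rc), Rc),
                 a * cc, tolerance = 1e-9)
  }
})

test_that("invertConcentration round-trips predictThickness", {
  expect_equal(invertConcentration(shellModel(0.033), 0, 650), 0)
  expect_equal(invertConcentration(0.05, 500, 500), 140)  # y = 7, 7/0.05
  h <- predictThickness(0.033, 30, 650)
  expect_equal(invertConcentration(0.033, h, 650), 30, tolerance = 1e-9)
  expect_error(invertConcentration(-0.033, 10, 650),
               class = "coreshell_domain")
})

test_that("fitAlpha recovers noiseless alpha exactly", {
  obs <- data.frame(conc_mM = c(10, 20), R_c_um = c(600, 900),
                    h_um = predictThickness(0.05, c(10, 20), c(600, 900)))
  expect_equal(alphaCoef(fitAlpha(obs)), 0.05)
  # any alpha, many observations, mixed radii
  set.seed(99)
  for (a in c(0.005, 0.033, 0.4)) {
    cc <- runif(30, 0.5, 120); Rc <- runif(30, 200, 1500)
    obs <- data.frame(conc_mM = cc, R_c_um = Rc,
                      h_um = predictThickness(a, cc, Rc))
    expect_equal(alphaCoef(fitAlpha(obs)), a, tolerance = 1e-9)
  }
})

test_that("fitAlpha equals the brute-force grid-search minimiser", {
  set.seed(2024)
  for (i in 1:5) {
    n <- sample(10:60, 1)
    cc <- runif(n, 0.5, 100); Rc <- runif(n, 300, 1200)
    h <- pmax(predictThickness(0.033, cc, Rc) + rnorm(n, sd = 5), 0)
    obs <- data.frame(conc_mM = cc, R_c_um = Rc, h_um = h)
    fitted <- alphaCoef(fitAlpha(obs))
    y <- linearizedResponse(h, Rc)
    expect_lt(abs(fitted - gridSearchAlpha(cc, y)), 1e-5)  # one grid step
    expect_lt(abs(fitted - 0.033) / 0.033, 0.10)
  }
})

test_that("fitAlpha handles zero-concentration rows and degenerate input", {
  base <- data.frame(conc_mM = c(10, 20), R_c_um = 700,
                     h_um = predictThickness(0.05, c(10, 20), 700))
  withZero <- rbind(base, data.frame(conc_mM = 0, R_c_um = 700, h_um = 0))
  expect_equal(alphaCoef(fitAlpha(withZero)), 0.05)  # x = 0: no leverage
  expect_error(fitAlpha(data.frame(conc_mM = c(0, 0), R_c_um = 700,
                                   h_um = c(0, 0))),
               class = "coreshell_degenerate")
  expect_error(fitAlpha(base[1, ]), class = "coreshell_degenerate")
})

test_that("per-concentration averaging is supported for the alpha fit", {
  cc <- rep(c(10, 20, 50), each = 3); Rc <- rep(700, 9)
  h <- predictThickness(0.04, cc, Rc)
  pooled <- fitAlpha(data.frame(conc_mM = cc, R_c_um = Rc, h_um = h))
  byConc <- fitAlpha(data.frame(conc_mM = cc, R_c_um = Rc, h_um = h),
                     pool = "byConcentration")
  expect_equal(alphaCoef(pooled), 0.04, tolerance = 1e-12)
  expect_equal(alphaCoef(byConc), 0.04, tolerance = 1e-12)
  expect_equal(byConc@n, 3L)
})
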