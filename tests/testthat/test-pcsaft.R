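comps3 <- function() asa_pcsaft_components()

random_state <- function() {
  # random ternary composition / temperature, density drawn by target
  # packing fraction so every state stays physical
  x <- runif(3); x <- x / sum(x)
  T <- runif(1, 280, 360)
  cc <- asa_pcsaft_components()
  msig3 <- sum(x * vapply(cc, `[[`, 0, "m") * vapply(cc, `[[`, 0, "sigma")^3)
  eta <- runif(1, 0.05, 0.5)
  rho_num <- 6 * eta / (pi * msig3)            # 1/A^3 (sigma bounds d above)
  rho <- rho_num / 6.02214076e23 * 1e27        # mol/L
  list(x = x, T = T, rho = rho)
}

test_that("residual Helmholtz energy vanishes in the ideal-gas limit", {
  mx <- pcsaft_mixture(comps3(), c(0.2, 0.3, 0.5), 298.15)
  expect_lt(abs(pcsaft_ares(mx, 1e-12)), 1e-9)
  expect_equal(pcsaft_z(mx, 1e-12), 1, tolerance = 1e-8)
  # the residual vanishes linearly in density
  expect_equal(pcsaft_ares(mx, 2e-6) / pcsaft_ares(mx, 1e-6), 2, tolerance = 1e-4)
  expect_error(pcsaft_ares(mx, 1e9), "packing")
})

test_that("zero association volume reproduces the non-associating model exactly", {
  toy <- toy_components()
  T <- 300
  for (rho in c(1, 8, 20)) {
    a_none <- pcsaft_ares(pcsaft_mixture(toy["plain"], 1, T), rho)
    a_gated <- pcsaft_ares(pcsaft_mixture(toy["gated"], 1, T), rho)
    expect_identical(a_gated, a_none)
  }
})

test_that("compressibility matches an independent central-difference check", {
  set.seed(101)
  for (k in 1:10) {
    s <- random_state()
    mx <- pcsaft_mixture(comps3(), s$x, s$T)
    z <- pcsaft_z(mx, s$rho)
    h <- s$rho * 1e-6   # near-optimal step for a plain central difference
    dnum <- (pcsaft_ares(mx, s$rho + h) - pcsaft_ares(mx, s$rho - h)) / (2 * h)
    expect_lt(abs(z - (1 + s$rho * dnum)), 1e-8)
    expect_true(is.finite(z))
  }
})

test_that("z is smooth and finite across the liquid density sweep", {
  mx <- pcsaft_mixture(comps3(), c(0.1, 0.45, 0.45), 298.15)
  rhos <- seq(0.5, 22, length.out = 60)
  zs <- vapply(rhos, function(r) pcsaft_z(mx, r), numeric(1))
  expect_true(all(is.finite(zs)))
  # no discontinuities: bounded curvature on the fine grid
  expect_lt(max(abs(diff(diff(zs)))), 0.2)
})

test_that("pure-solvent liquid densities land at the model's known values", {
  cc <- comps3()
  w <- pcsaft_mixture(cc["water"], 1, 298.15, 1.013)
  dw <- pcsaft_mass_density(w)
  # the 2B water parameter set underpredicts ambient liquid water density
  expect_equal(dw, 0.922, tolerance = 0.005)
  expect_lt(abs(dw - 0.997) / 0.997, 0.10)
  e <- pcsaft_mixture(cc["ethanol"], 1, 298.15, 1.013)
  expect_equal(pcsaft_mass_density(e), 0.78522, tolerance = 0.03)
})

test_that("the vapor branch is near-ideal at low pressure", {
  e <- pcsaft_mixture(comps3()["ethanol"], 1, 400, 0.1)
  rho <- pcsaft_density(e, "vapor")
  expect_equal(pcsaft_z(e, rho), 1, tolerance = 0.02)
})

test_that("density solving is deterministic and returns the requested branch", {
  mx <- pcsaft_mixture(comps3()[c("ethanol", "water")], c(0.4, 0.6), 298.15, 1.013)
  r1 <- pcsaft_density(mx, "liquid")
  r2 <- pcsaft_density(mx, "liquid")
  expect_identical(r1, r2)
  rv <- pcsaft_density(mx, "vapor")
  expect_lt(rv, r1)
  # the solved root reproduces the imposed pressure
  expect_equal(pcsaft_pressure(mx, r1), 1.013, tolerance = 1e-8)
})

test_that("permuting the component order permutes all outputs identically", {
  cc <- comps3()
  x <- c(0.1, 0.5, 0.4)
  mx <- pcsaft_mixture(cc, x, 310.15)
  mxp <- pcsaft_mixture(cc[c(3, 1, 2)], x[c(3, 1, 2)], 310.15)
  expect_equal(pcsaft_ares(mxp, 12), pcsaft_ares(mx, 12), tolerance = 1e-14)
  expect_equal(unname(pcsaft_lnphi(mxp)), unname(pcsaft_lnphi(mx))[c(3, 1, 2)],
               tolerance = 1e-10)
})

test_that("mixture fugacities collapse to the pure-component value at x = 1", {
  cc <- comps3()[c("ethanol", "water")]
  mx <- pcsaft_mixture(cc, c(1, 0), 298.15)
  pure <- pcsaft_mixture(cc["ethanol"], 1, 298.15)
  expect_equal(unname(pcsaft_lnphi(mx))[1], unname(pcsaft_lnphi(pure))[1],
               tolerance = 1e-7)
})

test_that("fugacity coefficients satisfy the Gibbs-Duhem relation", {
  set.seed(202)
  cc <- comps3()
  for (k in 1:5) {
    x <- runif(3, 0.05, 1); x <- x / sum(x)
    T <- runif(1, 285, 330)
    h <- 1e-4
    dir <- c(1, 0, -1)  # composition change at fixed T, P
    lp <- function(s) pcsaft_lnphi(pcsaft_mixture(cc, x + s * dir, T))
    # 4th-order stencil keeps the truncation error below the target
    dlp <- (8 * (lp(h) - lp(-h)) - (lp(2 * h) - lp(-2 * h))) / (12 * h)
    expect_lt(abs(sum(x * dlp)), 1e-5)
  }
})

test_that("activity coefficients behave in the pure and symmetric limits", {
  cc <- comps3()
  mx <- pcsaft_mixture(cc[c("ethanol", "water")], c(1 - 1e-9, 1e-9), 298.15)
  expect_equal(pcsaft_activity(mx, 1), 1, tolerance = 1e-6)
  # two identical components: every composition is the pure fluid
  twin <- list(cc$ethanol, cc$ethanol)
  for (x1 in c(0.2, 0.7)) {
    mx <- pcsaft_mixture(twin, c(x1, 1 - x1), 298.15)
    expect_equal(pcsaft_activity(mx, 1), 1, tolerance = 1e-7)
  }
  # water-ethanol at equimolar: positive, finite, reproducible
  mx <- pcsaft_mixture(cc[c("ethanol", "water")], c(0.5, 0.5), 298.15)
  g1 <- pcsaft_activity(mx, 1)
  g2 <- pcsaft_activity(mx, 1)
  expect_identical(g1, g2)
  expect_true(is.finite(g1) && g1 > 0)
})

test_that("component parameters round-trip through the JSON schema", {
  path <- system.file("extdata", "pcsaft_components.json", package = "cosolvr")
  cc <- read_pcsaft_components(path)
  ref_cc <- asa_pcsaft_components()
  expect_length(cc, 3)
  for (i in 1:3) {
    expect_equal(cc[[i]]$m, ref_cc[[i]]$m)
    expect_equal(cc[[i]]$kappa_ab, ref_cc[[i]]$kappa_ab)
    expect_equal(cc[[i]]$eps_ab_k, ref_cc[[i]]$eps_ab_k)
    expect_equal(cc[[i]]$assoc_scheme, ref_cc[[i]]$assoc_scheme)
  }
  tmp <- withr::local_tempfile(fileext = ".json")
  write_pcsaft_components(cc, tmp)
  cc2 <- read_pcsaft_components(tmp)
  expect_equal(cc2, cc)
})
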