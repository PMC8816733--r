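test_that("solubilization power follows the anchor ratio and log P relation", {
  expect_equal(loglinear_sigma(0.5, 0.5), 0)
  expect_equal(loglinear_sigma(ref$C1_25, ref$C2_25), 3.513848, tolerance = 1e-6)
  expect_lt(loglinear_sigma(0.1, 0.5), 0)
  expect_error(loglinear_sigma(-1, 0.5), "positive")
  expect_equal(loglinear_sigma_from_logP(ref$logP), 3.4452)
  expect_equal(loglinear_sigma_from_logP(0), 0.92)
  expect_equal(loglinear_sigma_from_logP(7, list(M = 0, N = 0.92)), 0.92)
})

test_that("log-linear predictions reproduce the reference ln C column", {
  s <- loglinear_sigma_from_logP(ref$logP)
  expect_equal(loglinear_predict(ref$C2_25, s, 0), ref$C2_25)
  expect_equal(log(loglinear_predict(ref$C2_25, s, 0.5)), -1.98, tolerance = 0.005)
  expect_equal(log(loglinear_predict(ref$C2_25, s, 1.0)), -0.26, tolerance = 0.005)
  expect_equal(log(loglinear_predict(ref$C2_37, s, 0)), -3.48, tolerance = 0.005)
})

test_that("Jouyban-Acree regression identifies noiseless coefficients", {
  J <- c(1000, -200, 50)
  f1 <- seq(0, 1, 0.1)
  grid <- expand.grid(f1 = f1, T = c(298.15, 310.15))
  C <- ja_predict(J, 0.8, 0.02, grid$f1, grid$T)
  fit <- ja_fit(data.frame(f1 = grid$f1, T = grid$T, C = C))
  expect_equal(unname(fit$J), J, tolerance = 1e-8)
  # fewer terms nest the same structure
  fit1 <- ja_fit(data.frame(f1 = f1, T = 298.15,
                            C = ja_predict(500, 0.8, 0.02, f1, 298.15)),
                 n_terms = 1)
  expect_equal(unname(fit1$J), 500, tolerance = 1e-8)
})

test_that("Jouyban-Acree fit on the reference data matches printed constants", {
  fit <- ja_fit(asa_ethanol_water())
  expect_equal(unname(fit$J), ref$J_printed, tolerance = 2e-3)
})

test_that("Jouyban-Acree degenerate designs raise informative errors", {
  expect_error(ja_fit(data.frame(f1 = c(0, 0.5, 1), T = 298.15,
                                 C = c(0.02, 0.1, 0.8)), n_terms = 3),
               "interior")
  expect_error(ja_fit(data.frame(f1 = c(0, 1), T = 298.15, C = c(0.02, 0.8))),
               "interior|anchor")
  expect_error(ja_fit(data.frame(f1 = seq(0.1, 0.9, 0.1), T = 298.15,
                                 C = rep(0.1, 9))),
               "anchor")
})

test_that("Jouyban-Acree predictions honor anchors and the mixing term", {
  J <- ref$J_printed
  expect_equal(ja_predict(J, 0.826, 0.0246, 0, 298.15), 0.0246)
  expect_equal(ja_predict(J, 0.826, 0.0246, 1, 298.15), 0.826)
  expect_equal(ja_predict(J, 0.826, 0.0246, 0.5, 298.15), 0.4714803,
               tolerance = 1e-6)
  # zero mixing coefficients reduce to the log-linear blend of anchors
  expect_equal(ja_predict(c(0, 0, 0), 0.8, 0.02, 0.3, 298.15),
               exp(0.3 * log(0.8) + 0.7 * log(0.02)))
})

test_that("fit residuals equal ln-scale prediction residuals (no leakage)", {
  d <- asa_ethanol_water()
  fit <- ja_fit(d)
  dd <- dataset_subset(d, "primary_solute")
  an <- fit$anchors
  pred <- ja_predict(fit, ifelse(dd$T == 298.15, an[["298.15"]][["C1"]], an[["310.15"]][["C1"]]),
                     ifelse(dd$T == 298.15, an[["298.15"]][["C2"]], an[["310.15"]][["C2"]]),
                     dd$f1, dd$T)
  expect_equal(log(dd$C) - log(pred), fit$residuals, tolerance = 1e-12)
})

test_that("pre-trained mixture models evaluate their coefficient algebra", {
  desc <- asa_abraham_descriptors()
  co <- ja_trained_coefficients("abraham")
  # power-0 coefficient is the dot product with (1, E, S, A, B, V)
  J0 <- sum(co$coefficients[[1]] * c(1, desc$E, desc$S, desc$A, desc$B, desc$V))
  expect_equal(J0, 937.1984, tolerance = 1e-4)
  expect_equal(ja_trained_predict(co, 0.826, 0.0246, 0, 298.15, desc), 0.0246)
  expect_equal(ja_trained_predict(co, 0.826, 0.0246, 1, 310.15, desc), 0.826)
  expect_error(ja_trained_predict(co, 0.826, 0.0246, 0.5, 298.15), "descriptors")
  # the solute-independent set is plain Jouyban-Acree with its constants
  gen <- ja_trained_coefficients("generic")
  expect_equal(
    ja_trained_predict(gen, 0.826, 0.0246, c(0.25, 0.5, 0.75), 298.15),
    ja_predict(c(1667.856, 1117.347, 447.7262), 0.826, 0.0246,
               c(0.25, 0.5, 0.75), 298.15))
})

test_that("minimal-training regression reproduces the published two-term set", {
  d <- asa_ethanol_water()
  sub <- dataset_subset(d, "primary_solute")
  keep <- sub$f1 %in% c(0, 1) | (sub$T == 298.15 & sub$f1 %in% c(0.3, 0.5, 0.7))
  fit <- ja_fit(as.data.frame(sub)[keep, ], n_terms = 2)
  expect_equal(unname(fit$J), c(1153.087, 474.742), tolerance = 5e-4)
})

test_that("modified Wilson predictions match hand evaluation and anchors", {
  expect_equal(wilson_predict(0.294, 3.405, ref$C1_37, ref$C2_37, 0.5),
               0.4495162, tolerance = 1e-6)
  expect_equal(wilson_predict(0.294, 3.405, ref$C1_37, ref$C2_37, 0), ref$C2_37)
  expect_equal(wilson_predict(0.294, 3.405, ref$C1_37, ref$C2_37, 1), ref$C1_37)
  # unity constants collapse to the log-linear blend
  f1 <- seq(0, 1, 0.25)
  expect_equal(wilson_predict(1, 1, 0.8, 0.02, f1),
               exp(f1 * log(0.8) + (1 - f1) * log(0.02)))
  expect_error(wilson_predict(-0.5, 2, 0.8, 0.02, 0.5), "lambda12")
})

test_that("Wilson fit recovers noiseless generating constants to 1e-6", {
  f1 <- seq(0, 1, 0.1)
  C <- wilson_predict(0.4, 2.5, 0.9, 0.03, f1)
  fit <- wilson_fit(data.frame(f1 = f1, T = 298.15, C = C))
  expect_equal(fit$lambda12, 0.4, tolerance = 1e-6)
  expect_equal(fit$lambda21, 2.5, tolerance = 1e-6)
})

test_that("Wilson fit on the 37C reference data recovers printed constants", {
  fit <- wilson_fit(asa37())
  expect_equal(fit$lambda12, ref$wilson_37[["lambda12"]], tolerance = 5e-3)
  expect_equal(fit$lambda21, ref$wilson_37[["lambda21"]], tolerance = 5e-3)
})

test_that("Wilson fit preconditions are enforced", {
  expect_error(wilson_fit(data.frame(f1 = 0.5, T = 298.15, C = 0.1)),
               "anchor|underdetermined")
  expect_error(wilson_fit(data.frame(f1 = c(0, 0.5, 1), T = 298.15,
                                     C = c(0.02, 0.3, 0.8))),
               "underdetermined")
  expect_error(wilson_fit(asa_ethanol_water()), "isothermal")
})

test_that("all models reproduce both anchors exactly across a seeded sweep", {
  set.seed(3)
  for (k in 1:10) {
    C1 <- runif(1, 0.1, 2); C2 <- runif(1, 0.001, 0.1)
    J <- rnorm(3, 0, 800)
    l <- runif(2, 0.2, 4)
    s <- loglinear_sigma(C1, C2)
    expect_equal(ja_predict(J, C1, C2, c(0, 1), 300), c(C2, C1))
    expect_equal(wilson_predict(l[1], l[2], C1, C2, c(0, 1)), c(C2, C1))
    expect_equal(loglinear_predict(C2, s, c(0, 1)), c(C2, C1))
    # exponentiated forms stay positive between the anchors
    f1 <- seq(0.1, 0.9, 0.2)
    expect_true(all(ja_predict(J, C1, C2, f1, 300) > 0))
    expect_true(all(wilson_predict(l[1], l[2], C1, C2, f1) > 0))
  }
})
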