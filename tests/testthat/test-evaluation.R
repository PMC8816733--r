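test_that("mean relative deviation follows its definition and invariances", {
  expect_equal(mrd_percent(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(mrd_percent(c(1, 2), c(2, 2)), 25)
  # scale invariance under common rescaling
  set.seed(5)
  calc <- runif(10, 0.5, 2); obs <- runif(10, 0.5, 2)
  expect_equal(mrd_percent(calc, obs), mrd_percent(1e3 * calc, 1e3 * obs))
  expect_error(mrd_percent(1:3, 1:4), "equal length")
  expect_error(mrd_percent(1, 0), "positive")
  expect_error(mrd_percent(numeric(0), numeric(0)), "at least one")
})

test_that("the log-linear predictive model scores 37.6% at 25C", {
  fit <- cosolv_fit(asa_ethanol_water(), "loglinear", sigma = "logP")
  rep_ <- summary(fit)$report
  expect_equal(unname(rep_$mrd_by_T[["298.15"]]), 37.6, tolerance = 0.002)
})

test_that("the fitted Jouyban-Acree model back-calculates to ~9.9% overall", {
  fit <- cosolv_fit(asa_ethanol_water(), "jouyban_acree")
  expect_equal(summary(fit)$report$mrd_overall, 9.9, tolerance = 0.01)
})

test_that("printed Wilson constants back-calculate to the printed MRD%", {
  d25 <- asa25(); d37 <- asa37()
  p25 <- wilson_predict(ref$wilson_25[["lambda12"]], ref$wilson_25[["lambda21"]],
                        ref$C1_25, ref$C2_25, d25$f1)
  p37 <- wilson_predict(ref$wilson_37[["lambda12"]], ref$wilson_37[["lambda21"]],
                        ref$C1_37, ref$C2_37, d37$f1)
  expect_equal(mrd_percent(p25, d25$C), 25.2, tolerance = 0.002)
  expect_equal(mrd_percent(p37, d37$C), 25.7, tolerance = 0.002)
})

test_that("prediction reports pool deviations and also average temperatures", {
  calc <- c(1.1, 0.9, 2.4)
  obs <- c(1, 1, 2)
  rep_ <- evaluate_predictions(calc, obs, f1 = c(0, 0.5, 0), T = c(298, 298, 310))
  expect_equal(rep_$mrd_overall, 100 * mean(c(0.1, 0.1, 0.2)))
  expect_equal(unname(rep_$mrd_by_T), c(10, 20))
  expect_equal(rep_$mrd_mean_of_T, 15)
  # perfect model scores zero everywhere
  perfect <- evaluate_predictions(obs, obs, T = c(298, 298, 310))
  expect_equal(perfect$mrd_overall, 0)
  expect_true(all(perfect$mrd_by_T == 0))
  expect_error(evaluate_predictions(1:2, 1:3), "align")
})

test_that("the measured profile peaks at f1 = 0.9 at both temperatures", {
  d <- asa_ethanol_water()
  expect_equal(solubility_peak(d, 298.15), 0.9)
  expect_equal(solubility_peak(d, 310.15), 0.9)
  mono <- solubility_dataset(
    data.frame(f1 = seq(0, 1, 0.25), T = 300, C = c(1, 2, 3, 4, 5) / 100))
  expect_equal(solubility_peak(mono, 300), 1.0)
  # ties return every tied fraction
  tied <- solubility_dataset(
    data.frame(f1 = c(0, 0.5, 1), T = 300, C = c(0.01, 0.05, 0.05)))
  expect_equal(solubility_peak(tied, 300), c(0.5, 1))
  expect_error(solubility_peak(d, 400), "at least two")
})

test_that("crystallinity index is a bounded area ratio", {
  expect_equal(crystallinity_percent(100, 100), 100)
  expect_equal(crystallinity_percent(25, 100), 25)
  expect_equal(crystallinity_percent(0, 10), 0)
  expect_error(crystallinity_percent(5, 0), "positive")
  expect_error(crystallinity_percent(11, 10), "crystalline area")
})

test_that("a known 40/60 crystalline/amorphous split is recovered", {
  # analytic Gaussian areas: height * width * sqrt(2*pi)
  h_peak <- 20 / (0.1 * sqrt(2 * pi))     # 20 area units per reflection
  h_halo <- 60 / (5 * sqrt(2 * pi))       # 60 area units of halo
  xr <- simulate_diffractogram(
    data.frame(position = c(7.8, 15.6), height = h_peak, width = 0.1),
    halo = c(20, h_halo, 5), noise_sd = 0.05, seed = 31)
  res <- diffractogram_crystallinity(xr$twotheta, xr$intensity)
  expect_equal(res$crystallinity_percent, 40, tolerance = 0.025)
  # noiseless pure halo has no crystalline area
  halo_only <- simulate_diffractogram(halo = c(20, h_halo, 5), noise_sd = 0)
  res0 <- diffractogram_crystallinity(halo_only$twotheta, halo_only$intensity)
  expect_lt(res0$crystallinity_percent, 0.5)
})

test_that("undersaturation flags compare measured against saturation series", {
  d <- dataset_subset(asa_ethanol_water(), "degradation_product", 298.15)
  flags <- undersaturation_check(data.frame(f1 = d$f1, C = d$C),
                                 sa_saturation_reference())
  expect_length(flags, 11)
  expect_true(all(flags))
  # boundary: equality is not undersaturation
  expect_false(undersaturation_check(1, 1))
  expect_length(undersaturation_check(numeric(0), numeric(0)), 0)
  expect_error(
    undersaturation_check(data.frame(f1 = c(0, 0.1), C = 1:2),
                          data.frame(f1 = c(0, 0.2), C_sat = 1:2)),
    "aligned")
})

test_that("the shipped crystallinity reference table is complete", {
  tab <- asa_crystallinity_reference()
  expect_equal(nrow(tab), 8)
  expect_true(all(tab$crystallinity_percent >= 0 & tab$crystallinity_percent <= 100))
  expect_equal(tab$crystallinity_percent[tab$sample == "water" & tab$T_C == 37], 23.1)
})

test_that("prediction reports serialize to CSV and JSON", {
  rep_ <- evaluate_predictions(c(1.1, 2.2), c(1, 2), f1 = c(0, 1), T = c(298, 298))
  csv <- withr::local_tempfile(fileext = ".csv")
  js <- withr::local_tempfile(fileext = ".json")
  write_prediction_report(rep_, csv, js)
  expect_equal(nrow(read.csv(csv)), 2)
  back <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_equal(back$mrd_overall, 10, tolerance = 1e-9)
})
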