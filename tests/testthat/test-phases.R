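# phase segmentation, growth rates, conversion rates, yields, balances

test_that("growth-rate estimation is exact on exponential data", {
  tt <- seq(0, 96, by = 24)
  s <- cultivation_series(data.frame(time_h = tt,
                                     dcw_g_l = 0.1 * exp(0.06 * tt),
                                     xylose_g_l = 70 - 0.2 * tt))
  expect_equal(estimate_mu(s, phase_row(0, 96)), 0.06, tolerance = 1e-12)
  # property: exact for arbitrary positive a and rate b
  set.seed(1)
  for (i in 1:10) {
    a <- runif(1, 0.01, 5); b <- runif(1, -0.1, 0.2)
    si <- cultivation_series(data.frame(time_h = tt,
                                        dcw_g_l = a * exp(b * tt),
                                        xylose_g_l = 70))
    expect_equal(estimate_mu(si, phase_row(0, 96)), b, tolerance = 1e-10)
  }
})

test_that("constant biomass yields zero growth rate", {
  s <- linear_series(seq(0, 72, 24), dcw = 2, conc = c(70, 60, 50, 40))
  expect_equal(estimate_mu(s, phase_row(0, 72)), 0)
})

test_that("growth-rate estimation requires three in-phase samples", {
  s <- linear_series(seq(0, 72, 24), dcw = 2, conc = c(70, 60, 50, 40))
  expect_error(estimate_mu(s, phase_row(0, 30)), "3 in-phase")
})

test_that("specific rate matches the hand-computed molar quotient", {
  # xylose 70 -> 49.9 g/L over 80 h at constant 1 g/L biomass:
  # (20.1 / 150.13 * 1000) / 80 / 1.0 = 1.6736 mmol/gDCW/h
  s <- linear_series(seq(0, 80, 20), dcw = 1,
                     conc = seq(70, 49.9, length.out = 5))
  r <- specific_rate(s, phase_row(0, 80), "xylose")
  expect_equal(r$rate, 20.1 / molar_mass("C5H10O5") * 1000 / 80,
               tolerance = 1e-10)
  expect_equal(r$rate, 1.674, tolerance = 1e-3)
  expect_equal(r$direction, "uptake")
})

test_that("flat concentrations give a zero rate with no direction", {
  s <- linear_series(seq(0, 80, 20), dcw = 1, conc = 30)
  r <- specific_rate(s, phase_row(0, 80), "xylose")
  expect_equal(r$rate, 0)
  expect_equal(r$direction, "none")
})

test_that("specific rate is antisymmetric under trajectory reversal", {
  set.seed(7)
  for (i in 1:5) {
    conc <- sort(runif(5, 10, 70), decreasing = TRUE)
    dcw <- exp(seq(0, 1, length.out = 5))
    tt <- seq(0, 80, 20)
    fwd <- cultivation_series(data.frame(time_h = tt, dcw_g_l = dcw,
                                         xylose_g_l = conc))
    rev_ <- cultivation_series(data.frame(time_h = tt, dcw_g_l = dcw,
                                          xylose_g_l = rev(conc)))
    rf <- specific_rate(fwd, phase_row(0, 80), "xylose")
    rr <- specific_rate(rev_, phase_row(0, 80), "xylose")
    expect_equal(rf$signed, -rr$signed, tolerance = 1e-10)
    expect_equal(rf$rate, rr$rate, tolerance = 1e-10)
  }
})

test_that("noiseless generated P1 recovers the reference uptake rate", {
  g <- generate_cultivation(generator_config(), seed = 1, noise = FALSE)
  ph <- segment_phases(g$series,
                       medium_nitrogen = g$truth$medium_nitrogen_mol,
                       biomass_n_fraction = g$truth$biomass_n_fraction)
  r <- specific_rate(g$series, ph[1, ], "xylose")
  expect_equal(r$rate, 1.74, tolerance = 0.02)
  expect_equal(estimate_mu(g$series, ph[1, ]), 0.060, tolerance = 1e-6)
})

test_that("segmentation recovers generator switch times within a sample interval", {
  g <- generate_cultivation(generator_config(), seed = 3, noise = FALSE)
  ph <- segment_phases(g$series,
                       medium_nitrogen = g$truth$medium_nitrogen_mol,
                       biomass_n_fraction = g$truth$biomass_n_fraction)
  expect_equal(nrow(ph), 3)
  expect_equal(ph$label, c("P1", "P2", "P3"))
  expect_lt(abs(ph$t_end[1] - g$truth$t_nitrogen), 24)
  expect_lt(abs(ph$t_end[2] - g$truth$t_xylose_depletion), 24)
  # phases partition the observed interval
  expect_equal(ph$t_start[1], g$series$samples$time_h[1])
  expect_equal(ph$t_end[3], max(g$series$samples$time_h))
  expect_equal(ph$t_start[-1], ph$t_end[-3])
})

test_that("nitrogen-replete series yields a single unlimited phase", {
  tt <- seq(0, 96, 24)
  s <- cultivation_series(data.frame(time_h = tt,
                                     dcw_g_l = 0.1 * exp(0.05 * tt),
                                     xylose_g_l = 70 - 0.05 * tt))
  ph <- segment_phases(s, medium_nitrogen = 1, biomass_n_fraction = 0.0075)
  expect_equal(nrow(ph), 1)
  expect_equal(ph$label, "P1")
  expect_equal(ph$limitation, "none")
})

test_that("nitrogen exhaustion falls at ~23 g/L xylose consumed in the reference medium", {
  g <- generate_cultivation(generator_config(), seed = 1, noise = FALSE)
  expect_equal(g$truth$xylose_consumed_at_nitrogen, 23, tolerance = 0.05)
  # the detected boundary agrees with the generator switch
  ph <- segment_phases(g$series,
                       medium_nitrogen = g$truth$medium_nitrogen_mol,
                       biomass_n_fraction = g$truth$biomass_n_fraction,
                       criterion = "nitrogen")
  expect_lt(abs(ph$t_end[1] - g$truth$t_nitrogen), 3)
})

test_that("series without growth are rejected", {
  s <- linear_series(seq(0, 72, 24), dcw = 2, conc = c(70, 60, 50, 40))
  expect_error(segment_phases(s), "no growth")
})

test_that("yields and volumetric rates follow the published arithmetic", {
  # 20.7 mg/L carotenoid over 71.4 g/L substrate -> Y_S = 0.29 mg/g
  tt <- seq(0, 168, 24)
  df <- data.frame(time_h = tt,
                   dcw_g_l = seq(0.5, 24.9, length.out = 8),
                   xylose_g_l = seq(70, 0, length.out = 8),
                   xylitol_g_l = seq(0, 1.4, length.out = 8),
                   carotenoid_mg_l = seq(0, 20.7, length.out = 8),
                   lipid_g_l = seq(0, 8.1, length.out = 8))
  s <- cultivation_series(df)
  y <- yields_and_q(s, phase = NULL)
  car <- y[y$product == "carotenoid", ]
  expect_equal(car$Y_S, 20.7 / 70, tolerance = 1e-10)
  expect_equal(round(car$Y_S, 2), 0.30)  # consumed xylose alone: 70 g/L
  expect_equal(car$Y, 20.7 / 24.4, tolerance = 1e-10)
  expect_equal(car$q, 20.7 / 168, tolerance = 1e-10)
  # with 71.4 g/L total substrate consumed the ratio prints as 0.29
  expect_equal(round(20.7 / 71.4, 2), 0.29)
})

test_that("zero product change gives zero yields and rate", {
  s <- linear_series(seq(0, 72, 24), dcw = c(1, 2, 4, 8),
                     conc = c(70, 60, 50, 40))
  s$samples$carotenoid_mg_l <- 5
  s$samples$lipid_g_l <- 1
  y <- yields_and_q(s, phase = NULL)
  expect_true(all(y$Y == 0))
  expect_true(all(y$Y_S == 0))
  expect_true(all(y$q == 0))
})

test_that("yields are flagged when biomass declines", {
  s <- linear_series(seq(0, 72, 24), dcw = c(8, 6, 4, 2),
                     conc = c(70, 60, 50, 40))
  s$samples$carotenoid_mg_l <- seq(0, 9, 3)
  y <- yields_and_q(s, phase = NULL)
  expect_true(all(grepl("undefined", y$Y_flag)))
  expect_true(all(is.na(y$Y)))
})

test_that("noiseless generator yields are recovered exactly", {
  g <- generate_cultivation(generator_config(), seed = 2, noise = FALSE)
  ph <- segment_phases(g$series,
                       medium_nitrogen = g$truth$medium_nitrogen_mol,
                       biomass_n_fraction = g$truth$biomass_n_fraction)
  rs <- phase_rates(g$series, ph[1, ])
  expect_equal(rs$mu, g$truth$mu[1], tolerance = 1e-9)
  expect_equal(rs$r$xylose$rate, g$truth$r_xyl[1], tolerance = 1e-9)
  expect_equal(rs$yield_biomass, g$truth$yield_biomass[1], tolerance = 1e-6)
  # secretion yields: xylitol/arabitol per consumed xylose
  expect_equal(rs$r$arabitol$rate / rs$r$xylose$rate,
               g$truth$y_abt * 150.13 / 152.146, tolerance = 1e-9)
})

test_that("carbon balance closes exactly on a hand-closed rate set", {
  # all consumed carbon ends in biomass and CO2 by construction
  reg <- compound_registry()
  bc <- attr(reg, "biomass_carbon")
  mu <- 0.05
  uptake <- 1
  c_bio <- mu * bc / 12.011 * 1000
  rs <- structure(list(
    phase = phase_row(0, 10), mu = mu,
    r = list(xylose = list(rate = uptake, direction = "uptake",
                           signed = -uptake)),
    r_car = 0, r_lip = 0,
    r_co2 = uptake * 5 - c_bio,
    mean_dcw = 1), class = "rate_set")
  cb <- carbon_balance(rs, reg)
  expect_equal(cb$recovery, 1, tolerance = 1e-12)
  expect_equal(cb$flag, "")
})

test_that("carbon balance is 1 on noise-free generator output in every phase", {
  g <- generate_cultivation(generator_config(), seed = 4, noise = FALSE)
  fit <- fit_physiology(g$series,
                        medium_nitrogen = g$truth$medium_nitrogen_mol,
                        biomass_n_fraction = g$truth$biomass_n_fraction)
  for (ph in names(fit$carbon)) {
    expect_equal(fit$carbon[[ph]]$recovery, 1, tolerance = 1e-6)
  }
})

test_that("published reference-phase rates reproduce the ~93% carbon balance", {
  # transcription of the printed P1 physiology: biomass yield 0.25 g/g,
  # one-third of consumed carbon in polyols, one-third in CO2
  reg <- compound_registry()
  uptake <- 1.74
  c_in <- uptake * 5
  mu <- 0.060
  r_lip <- 0.18 * mu                      # steady 0.18 g/gDCW content
  polyol <- 0.30 * c_in / 5               # 30% of carbon as C5 polyols
  rs <- structure(list(
    phase = phase_row(0, 70), mu = mu,
    r = list(xylose = list(rate = uptake, direction = "uptake",
                           signed = -uptake),
             xylitol = list(rate = polyol / 3, direction = "production",
                            signed = polyol / 3),
             arabitol = list(rate = 2 * polyol / 3, direction = "production",
                             signed = 2 * polyol / 3)),
    r_car = 0.042, r_lip = r_lip,
    r_co2 = 0.33 * c_in,
    mean_dcw = 1), class = "rate_set")
  cb <- carbon_balance(rs, reg)
  expect_equal(cb$recovery, 0.93, tolerance = 0.015)
})

test_that("half-unmeasured substrate carbon shows up as a 0.5 recovery", {
  g <- generate_cultivation(generator_config(unmeasured_fraction = 0.5),
                            seed = 1, noise = FALSE)
  fit <- fit_physiology(g$series,
                        medium_nitrogen = g$truth$medium_nitrogen_mol,
                        biomass_n_fraction = g$truth$biomass_n_fraction)
  expect_equal(fit$carbon$P1$recovery, 0.5, tolerance = 0.01)
})

test_that("missing off-gas flags a CO2-less balance", {
  g <- generate_cultivation(generator_config(), seed = 1, noise = FALSE)
  g$series$samples$co2_mmol_l_h <- NULL
  fit <- fit_physiology(g$series,
                        medium_nitrogen = g$truth$medium_nitrogen_mol,
                        biomass_n_fraction = g$truth$biomass_n_fraction)
  expect_equal(fit$carbon$P1$flag, "co2_less")
  expect_lt(fit$carbon$P1$recovery, 1)
})

test_that("physiology fit methods expose growth rates and predictions", {
  g <- generate_cultivation(generator_config(), seed = 6, noise = FALSE)
  fit <- fit_physiology(g$series,
                        medium_nitrogen = g$truth$medium_nitrogen_mol,
                        biomass_n_fraction = g$truth$biomass_n_fraction)
  mus <- coef(fit)
  expect_named(mus, c("P1", "P2", "P3"))
  expect_equal(unname(mus), g$truth$mu, tolerance = 1e-6)
  pred <- predict(fit)
  expect_equal(pred, g$series$samples$dcw_g_l, tolerance = 0.02)
  expect_output(print(fit), "P1")
  expect_output(print(summary(fit)), "Whole-batch")
})
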