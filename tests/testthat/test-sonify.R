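test_that("regional averages use only labelled, unmasked pixels", {
  sl <- tiny_slice(fl = 100, pl = 150, smc = 180)
  lab <- segment_lobes(sl, tiny_boundaries())
  fl <- region_average(sl, lab, "frontal")
  expect_equal(fl$mean, 100)
  expect_equal(fl$n, 4 * 3)

  # two-value region averages to the midpoint
  sl2 <- tiny_slice(fl = 100)
  sl2$values[2:5, 2:4] <- rep(c(80, 120), 6)
  expect_equal(region_average(sl2, lab, "frontal")$mean, 100)

  # masking removes pixels from the average
  sl3 <- apply_mask(tiny_slice(fl = 100, pl = 150, smc = 180), 120)
  expect_error(region_average(sl3, lab, "frontal"),
               "frontal.*no surviving")
  expect_equal(region_average(sl3, lab, "parietal")$mean, 150)
})

test_that("regional averages agree with a brute-force sum/count loop", {
  set.seed(31)
  b <- tiny_boundaries()
  for (rep in 1:5) {
    v <- matrix(sample(0:255, 8 * 14, TRUE), 8, 14)
    sl <- apply_mask(slice_grid(v, bit_depth = 8), 60)
    lab <- segment_lobes(sl, b)
    for (nm in c("frontal", "parietal", "sensorimotor")) {
      code <- c(frontal = 1L, parietal = 2L, sensorimotor = 3L)[[nm]]
      want <- brute_region_mean(v, sl$mask, unclass(lab), code)
      got <- region_average(sl, lab, nm)
      expect_identical(got$mean, want$mean)
      expect_identical(got$n, want$n)
    }
  }
})

test_that("relative deviation is the absolute normalized difference", {
  expect_equal(relative_deviation(100, 100), 0)
  expect_equal(relative_deviation(75, 100), 0.25)
  expect_equal(relative_deviation(125, 100), 0.25)
  expect_error(relative_deviation(50, 0), "positive")
})

test_that("the severity table maps to the standard detune factors", {
  expect_equal(severity_to_detune("normal"), 0.05)
  expect_equal(severity_to_detune("mild"), 0.10)
  expect_equal(severity_to_detune("moderate"), 0.15)
  expect_equal(severity_to_detune("severe"), 0.20)
  expect_error(severity_to_detune("very severe"), "unknown severity")
})

test_that("frequency mapping follows f = 440 * (1 +/- DF * |delta|)", {
  # no deviation: all three tones at the base frequency
  ts0 <- tts_frequencies(list(av_fl = 100, av_pl = 100, av_smc = 100), 0.2)
  expect_equal(unname(c(ts0$f_smc, ts0$f_fl, ts0$f_pl)), rep(440, 3))

  ts1 <- tts_frequencies(list(av_fl = 75, av_pl = 100, av_smc = 100), 0.20)
  expect_equal(ts1$delta_fl, 0.25)
  expect_equal(ts1$f_fl, 440 * 1.05)          # 462 Hz

  ts2 <- tts_frequencies(list(av_fl = 100, av_pl = 80, av_smc = 100), 0.10)
  expect_equal(ts2$delta_pl, 0.20)
  expect_equal(ts2$f_pl, 440 * 0.98)          # 431.2 Hz

  # compatibility variant: parietal deviation applied upward
  ts3 <- tts_frequencies(list(av_fl = 100, av_pl = 80, av_smc = 100), 0.10,
                         parietal_sign = "positive")
  expect_equal(ts3$f_pl, 440 * 1.02)

  expect_error(
    tts_frequencies(list(av_fl = 100, av_pl = 1, av_smc = 100), detune = 2),
    "frequency collapse")
})

test_that("frequency mapping is monotone, scale-invariant, and collapse-proof", {
  stats_for <- function(dev) list(av_fl = 100 * (1 - dev),
                                  av_pl = 100 * (1 - dev), av_smc = 100)
  devs <- c(0, 0.05, 0.1, 0.2, 0.4)
  f_fl <- vapply(devs, function(d) tts_frequencies(stats_for(d), 0.15)$f_fl, 1)
  f_pl <- vapply(devs, function(d) tts_frequencies(stats_for(d), 0.15)$f_pl, 1)
  expect_true(all(diff(f_fl) > 0))
  expect_true(all(diff(f_pl) < 0))
  dfs <- c(0.05, 0.10, 0.15, 0.20)
  by_df <- vapply(dfs, function(df)
    tts_frequencies(stats_for(0.25), df)$f_fl, 1)
  expect_true(all(diff(by_df) > 0))

  # intensity units cancel: scaling all means leaves the tones unchanged
  s <- list(av_fl = 70, av_pl = 85, av_smc = 110)
  s10 <- lapply(s, `*`, 10)
  expect_equal(tts_frequencies(s, 0.2)[c("f_smc", "f_fl", "f_pl")],
               tts_frequencies(s10, 0.2)[c("f_smc", "f_fl", "f_pl")])

  # equal-magnitude deviations still yield three distinct tones
  eq <- tts_frequencies(list(av_fl = 80, av_pl = 80, av_smc = 100), 0.2)
  expect_true(eq$f_fl != eq$f_pl)
  expect_equal(unname(beat_rates(eq)[c("fl_smc", "smc_pl")]),
               rep(440 * 0.2 * 0.2, 2))
})

test_that("sonify_slice wires masking, segmentation, and mapping together", {
  sl <- tiny_slice(fl = 150, pl = 120, smc = 200, bg = 30)
  fit <- sonify_slice(sl, tiny_boundaries(), detune = 0.2)
  expect_s3_class(fit, "tts")
  expect_equal(fit$threshold, 0.45 * 255)
  expect_equal(fit$stats$av_smc, 200)
  expect_equal(fit$tones$delta_fl, 0.25)
  expect_equal(fit$tones$delta_pl, 0.40)
  expect_equal(unname(coef(fit)),
               c(440, 440 * 1.05, 440 * (1 - 0.2 * 0.4)))

  # severity and detune are exclusive
  expect_error(sonify_slice(sl, tiny_boundaries()), "exactly one")
  expect_error(sonify_slice(sl, tiny_boundaries(), severity = "mild",
                            detune = 0.1), "exactly one")

  s <- summary(fit)
  expect_s3_class(s, "summary.tts")
  expect_equal(s$regions$n_pixels, c(12, 12, 12))
  expect_output(print(fit), "f_SMC = 440")
})

test_that("the sonification report is a faithful JSON audit trail", {
  sl <- tiny_slice(fl = 150, pl = 120, smc = 200, bg = 30)
  fit <- sonify_slice(sl, tiny_boundaries(), severity = "severe")
  f <- withr::local_tempfile(fileext = ".json")
  sonification_report(fit, f)
  rep <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(rep$av_SMC, 200)
  expect_equal(rep$delta_PL, 0.4)
  expect_equal(rep$detune_factor, 0.2)
  expect_equal(rep$severity, "severe")
  expect_equal(rep$f_FL, 440 * 1.05)
  expect_equal(rep$mask_threshold, 114.75)
})
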