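# Morlet time-frequency energy, band averages, responsible leads, lobes

test_that("a 60 Hz tone localizes at 60 Hz with calibrated power", {
  fs <- 1000
  t <- (0:3999) / fs
  tf <- morlet_tfr(sin(2 * pi * 60 * t), fs, seq(40, 78, 2))
  tmean <- rowMeans(tf$power[, 1000:3000])
  expect_equal(tf$freqs[which.max(tmean)], 60)
  expect_equal(max(tmean), 0.5, tolerance = 0.01)  # a^2/2 for a = 1
  # frequency-independent normalization
  for (f0 in c(100, 250)) {
    tf2 <- morlet_tfr(sin(2 * pi * f0 * t), fs, f0)
    expect_equal(mean(tf2$power[1, 1000:3000]), 0.5, tolerance = 0.025)
  }
  expect_error(morlet_tfr(t, fs, 600), "Nyquist")
})

test_that("zero signal gives an all-zero map and quadratic amplitude scaling holds", {
  fs <- 1000
  tf0 <- morlet_tfr(rep(0, 2000), fs, c(60, 100))
  expect_true(all(tf0$power == 0))

  t <- (0:2999) / fs
  x <- sin(2 * pi * 60 * t)
  e1 <- average_band_energy(morlet_tfr(x, fs, seq(40, 78, 2)), "gamma")
  for (a in c(0.5, 2, 3)) {
    ea <- average_band_energy(morlet_tfr(a * x, fs, seq(40, 78, 2)), "gamma")
    expect_equal(ea / e1, a^2, tolerance = 0.0001)
  }
})

test_that("band leakage of a tone is small and band energy is time-shift stable", {
  fs <- 1000
  t <- (0:3999) / fs
  x <- sin(2 * pi * 60 * t)
  eg <- mean(scalpHFO:::morlet_power_means(x, fs, band_freq_grid("gamma")))
  er <- mean(scalpHFO:::morlet_power_means(x, fs, band_freq_grid("ripple")))
  expect_lt(er, 0.05 * eg)

  # shifted burst away from edges: band energy within 2%
  bg <- rep(0, 6000)
  mk <- function(t0) {
    r <- eeg_recording(matrix(bg, ncol = 1), "Cz", fs)
    inject_burst(r, "Cz", t0, 60, 8, 20)$recording$data[, 1]
  }
  e_a <- mean(scalpHFO:::morlet_power_means(mk(2.0), fs, band_freq_grid("gamma")))
  e_b <- mean(scalpHFO:::morlet_power_means(mk(3.5), fs, band_freq_grid("gamma")))
  expect_lt(abs(e_a - e_b) / e_a, 0.02)
})

test_that("white-noise gamma energy is stable across seeds", {
  # ~16 s gives ~640 independent gamma-band samples, so seed-to-seed spread
  # stays well inside +/- 15% of the mean
  es <- vapply(1:10, function(s) {
    bg <- generate_background(16, 1000, "Cz", 15, seed = 700 + s)
    mean(scalpHFO:::morlet_power_means(bg$data[, 1], 1000,
                                       band_freq_grid("gamma")))
  }, numeric(1))
  expect_lt(max(abs(es - mean(es))) / mean(es), 0.15)
})

test_that("channel_band_energies yields one row per subject x channel x state x band", {
  cfg <- cohort_config(
    n_subjects_per_group = 1, groups = "NC",
    states = list(NC = c("wake", "sleep")),
    segment_duration = c(wake = 2, sleep = 2),
    channels = channels_1020(), event_rate = 0, seed = 3)
  co <- generate_cohort(cfg)
  tab <- channel_band_energies(co$segments,
                               freq_step = c(gamma = 4, ripple = 10,
                                             fast_ripple = 10))
  expect_equal(nrow(tab), 19 * 2 * 3)
  expect_true(all(tab$avg_energy >= 0))
  expect_equal(anyDuplicated(tab[, c("subject", "channel", "state", "band")]), 0)

  expect_equal(nrow(channel_band_energies(list())), 0)
  seg <- eeg_segment(matrix(rnorm(1000), ncol = 1), "Cz", 1000)
  expect_error(channel_band_energies(list(seg)), "metadata")
})

test_that("a sleep-attenuated cohort recovers sleep < wake in every band", {
  be <- expand.grid(group = "NC", state = "wake",
                    band = c("gamma", "ripple", "fast_ripple"),
                    stringsAsFactors = FALSE)
  be$factor <- 4
  cfg <- cohort_config(
    n_subjects_per_group = 4, groups = "NC",
    states = list(NC = c("wake", "sleep")),
    segment_duration = c(wake = 4, sleep = 4),
    channels = c("C3", "C4"), event_rate = 450,
    band_effects = be, seed = 11)
  co <- generate_cohort(cfg)
  tab <- channel_band_energies(co$segments,
                               freq_step = c(gamma = 4, ripple = 10,
                                             fast_ripple = 10))
  for (b in unique(tab$band)) {
    expect_lt(median(tab$avg_energy[tab$band == b & tab$state == "sleep"]),
              median(tab$avg_energy[tab$band == b & tab$state == "wake"]))
  }
})

test_that("responsible leads rank by pooled energy with documented tie-breaks", {
  tab <- expand.grid(subject = c("IS01", "IS02"), channel = c("T3", "C3", "O1"),
                     state = "wake", band = c("gamma", "ripple"),
                     stringsAsFactors = FALSE)
  tab$group <- "IS"
  tab$avg_energy <- 1
  tab$avg_energy[tab$channel == "T3"] <- 5
  ls <- responsible_leads(tab, top_k = 1)
  expect_true(all(ls$leads$channel == "T3"))
  expect_true(all(ls$leads$lobe == "temporal"))
  expect_equal(unname(ls$lobe_counts["temporal"]), 2)
  expect_equal(sum(ls$lobe_counts), nrow(ls$leads))

  # all-equal energies: canonical 10-20 order wins and the tie is flagged
  tab$avg_energy <- 1
  ls2 <- responsible_leads(tab, top_k = 1)
  expect_true(all(ls2$leads$channel == "C3"))  # C3 precedes T3/O1 canonically
  expect_true(all(ls2$leads$tie))
  expect_error(responsible_leads(tab, top_k = 0), "top_k")
})

test_that("temporal-weighted injections put the plurality of leads in the temporal lobe", {
  w <- setNames(rep(1, 19), channels_1020())
  w[c("T3", "T4", "T5", "T6")] <- 12
  cfg <- cohort_config(
    n_subjects_per_group = 5, groups = "IS", states = list(IS = "wake"),
    segment_duration = c(wake = 3), channels = channels_1020(),
    event_rate = 1200, channel_weights = w, seed = 12)
  co <- generate_cohort(cfg)
  tab <- channel_band_energies(co$segments,
                               freq_step = c(gamma = 4, ripple = 10,
                                             fast_ripple = 10))
  ls <- responsible_leads(tab, top_k = 1)
  expect_equal(names(which.max(ls$lobe_counts)), "temporal")
})

test_that("lobe_of maps 10-20 labels and rejects unknown ones", {
  expect_identical(lobe_of("T5"), "temporal")
  expect_identical(lobe_of("Fp2"), "frontal")
  expect_identical(lobe_of(c("Cz", "P3", "O2")),
                   c("central", "parietal", "occipital"))
  expect_error(lobe_of("X9"), "unknown 10-20")
})
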