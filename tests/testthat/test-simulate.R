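test_that("identical seeds give bit-identical cohorts", {
  cfg <- simulation_config(n_animals_per_genotype = 1, n_roi = 12, seed = 9)
  s1 <- simulate_cohort(cfg)
  s2 <- simulate_cohort(cfg)
  expect_identical(s1$tsset$animals[["WT01"]]$signal,
                   s2$tsset$animals[["WT01"]]$signal)
  expect_identical(s1$tsset$animals[["KO01"]]$signal,
                   s2$tsset$animals[["KO01"]]$signal)
  s3 <- simulate_cohort(simulation_config(n_animals_per_genotype = 1,
                                          n_roi = 12, seed = 10))
  expect_false(identical(s1$tsset$animals[["WT01"]]$signal,
                         s3$tsset$animals[["WT01"]]$signal))
})

test_that("invalid configurations are rejected", {
  expect_error(simulation_config(vehicle_onset_s = 3000, drug_onset_s = 1200),
               "onsets")
  expect_error(simulation_config(duration_s = 4800.5), "integer multiple")
  expect_error(simulation_config(within_block_r = 0.1, between_block_r = 0.4),
               "exceed")
  # per-ROI effect loadings exceeding the unique-variance budget -> non-PSD
  expect_error(simulation_config(
    within_block_r = 0.5,
    drug_effect_edges = data.frame(i = c(1, 1), j = c(7, 8),
                                   delta = c(0.4, 0.4))),
    "positive semi-definite")
})

test_that("drug envelope is causal, unit-peaked, and halves per half-life", {
  tau <- 60; hl <- 780
  expect_equal(drug_envelope(c(-100, -1, 0), tau, hl), c(0, 0, 0))
  expect_true(all(drug_envelope(c(1, 10, 1000, 4000), tau, hl) > 0))
  tpk <- drug_envelope_peak_time(tau, hl)
  expect_equal(drug_envelope(tpk, tau, hl), 1, tolerance = 1e-12)
  grid <- seq(1, 4000, by = 1)
  expect_lte(max(drug_envelope(grid, tau, hl)), 1 + 1e-12)
  # asymptotic halving well past the peak (rise term ~1 there)
  t0 <- tpk + 3 * tau + 1000
  ratio <- drug_envelope(t0 + hl, tau, hl) / drug_envelope(t0, tau, hl)
  expect_equal(ratio, 0.5, tolerance = 1e-3)
})

test_that("stationary empirical FC converges to the analytic block target", {
  cfg <- clean_null_config(n_animals_per_genotype = 2, n_roi = 12,
                           vehicle_onset_s = 3000, drug_onset_s = 3600,
                           seed = 7)
  sim <- simulate_cohort(cfg)
  tgt <- analytic_target_corr(cfg, "WT", 0)
  wt <- grep("^WT", names(sim$tsset$animals), value = TRUE)
  rbar <- Reduce(`+`, lapply(wt, function(id)
    stats::cor(t(sim$tsset$animals[[id]]$signal[, 1:3000])))) / length(wt)
  # tolerance: 3 x Fisher-z SE for a band-limited 3000-s segment
  tol <- 3 / sqrt(2 * 0.092 * 3000)
  expect_lt(max(abs(rbar - tgt)[upper.tri(tgt)]), tol)
})

test_that("drug-edge modulation rises in WT only and relaxes toward baseline", {
  sim <- default_sim()
  cfg <- sim$truth$config
  ed <- sim$truth$modulated_edges
  env1 <- mean(drug_envelope(seq(0, 599), cfg$drug_onset_tau_s,
                             cfg$drug_decay_halflife_s))
  mean_edge_r <- function(geno, samples) {
    ids <- grep(paste0("^", geno), names(sim$tsset$animals), value = TRUE)
    sapply(seq_len(nrow(ed)), function(k) {
      mean(sapply(ids, function(id) {
        x <- sim$tsset$animals[[id]]$signal
        stats::cor(x[ed$i[k], samples], x[ed$j[k], samples])
      }))
    })
  }
  drug1 <- 3001:3600
  base <- 1:1200
  r_wt <- mean_edge_r("WT", drug1)
  r_wt_base <- mean_edge_r("WT", base)
  r_ko <- mean_edge_r("KO", drug1)
  # raw (unpreprocessed) signals carry shared nuisance/drift, so compare
  # drug-interval FC against each genotype's own baseline FC
  shift_wt <- r_wt - r_wt_base
  expect_true(all(sign(shift_wt) == sign(ed$delta)))
  expect_true(all(abs(shift_wt) > 0.35 * env1 * abs(ed$delta)))
  expect_lt(max(abs(r_ko - mean_edge_r("KO", base))), 0.15)
  # relaxation: terminal drug interval closer to baseline than the first
  drug3 <- 4201:4800
  r_wt3 <- mean_edge_r("WT", drug3)
  expect_true(mean(abs(r_wt3 - r_wt_base)) < 0.6 * mean(abs(shift_wt)))
})

test_that("genotypes share latent streams: identical except modulated components", {
  cfg <- simulation_config(n_animals_per_genotype = 1, seed = 21,
    oscillators = local({
      o <- data.frame(band = "slow5", freq_hz = 0.018, amplitude = 0.6,
                      gain_wt_drug = 1, gain_ko_drug = 1)
      attr(o, "rois") <- 25:30
      o
    }))
  sim <- simulate_cohort(cfg)
  wt <- sim$tsset$animals[["WT01"]]$signal
  ko <- sim$tsset$animals[["KO01"]]$signal
  ed <- sim$truth$modulated_edges
  touched <- sort(unique(c(ed$i, ed$j)))
  expect_identical(wt[-touched, ], ko[-touched, ])
  expect_false(any(apply(wt[touched, ] == ko[touched, ], 1, all)))
})

test_that("table export/read roundtrip preserves the cohort", {
  dir <- withr::local_tempdir()
  cfg <- simulation_config(n_animals_per_genotype = 1, n_roi = 12, seed = 3)
  sim <- simulate_cohort(cfg)
  export_cohort(sim$tsset, dir, format = "table")
  meta <- jsonlite::read_json(file.path(dir, "cohort.json"),
                              simplifyVector = TRUE)
  expect_length(meta$roi_labels, 12)
  tab <- utils::read.delim(file.path(dir, "WT01.tsv"), check.names = FALSE)
  expect_equal(nrow(tab), 4800)
  back <- read_cohort(dir)
  expect_lt(max(abs(back$animals[["WT01"]]$signal -
                    sim$tsset$animals[["WT01"]]$signal)), 1e-6)
  expect_equal(back$tr_s, sim$tsset$tr_s)
  expect_equal(back$animals[["KO01"]]$genotype, "KO")
  expect_error(export_cohort(sim$tsset, dir, format = "hdf5"))
})

test_that("volume export roundtrips through atlas extraction", {
  dir <- withr::local_tempdir()
  cfg <- simulation_config(n_animals_per_genotype = 1, n_roi = 8,
                           duration_s = 1200, vehicle_onset_s = 300,
                           drug_onset_s = 600, seed = 4)
  sim <- simulate_cohort(cfg)
  export_cohort(sim$tsset, dir, format = "volume")
  back <- read_cohort(dir)
  expect_lt(max(abs(back$animals[["WT01"]]$signal -
                    sim$tsset$animals[["WT01"]]$signal)), 1e-6)
})

test_that("oscillator condition gain raises band power by the configured factor", {
  sim <- default_sim()
  cfg <- sim$truth$config
  osc <- cfg$oscillators[cfg$oscillators$band == "slow5", ]
  gain <- osc$gain_wt_drug
  expect_gt(gain, 1)
  seg <- segment_conditions(sim$tsset)
  roi <- cfg$oscillator_rois[1]
  excess <- sapply(grep("^WT", names(sim$tsset$animals), value = TRUE),
    function(id) {
      x <- sim$tsset$animals[[id]]$signal[roi, ]
      pv <- welch_psd(x[condition_samples(seg, "vehicle")], cfg$tr_s)
      pd <- welch_psd(x[condition_samples(seg, "drug")], cfg$tr_s)
      pd$band_powers[["slow5"]] - pv$band_powers[["slow5"]]
    })
  injected <- (gain - 1) * osc$amplitude^2 / 2
  expect_equal(mean(excess), injected, tolerance = 0.25)
  # KO has no gain: no systematic excess
  excess_ko <- sapply(grep("^KO", names(sim$tsset$animals), value = TRUE),
    function(id) {
      x <- sim$tsset$animals[[id]]$signal[roi, ]
      pv <- welch_psd(x[condition_samples(seg, "vehicle")], cfg$tr_s)
      pd <- welch_psd(x[condition_samples(seg, "drug")], cfg$tr_s)
      pd$band_powers[["slow5"]] - pv$band_powers[["slow5"]]
    })
  expect_lt(abs(mean(excess_ko)), injected / 3)
})
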