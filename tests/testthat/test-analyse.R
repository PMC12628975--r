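# End-to-end pipeline and command-line interface.

test_that("a fluxless recording analyses to zero flux", {
  sc <- simulation_scenario(true_flux = 0, n_loops = 5,
                            electrode = list(tau = 0.5, drift = 1,
                                             noise_sd = 0))
  rec <- simulate_recording(sc)$recording
  res <- analyse_recording(rec, ideal_cal(),
                           flux_config("diffusion_gradient", "K+"))
  expect_equal(nrow(res), 5)
  expect_true(all(abs(res$flux1_nmol_m2_s[2:4]) < 1e-6))
  expect_true(all(is.na(res$flux1_nmol_m2_s[c(1, 5)])))
})

test_that("known efflux is recovered by both methods", {
  sim <- simulate_recording(recovery_scenario(tau = 0.5, drift = 0,
                                              noise_sd = 0))
  true_nmol <- sim$truth$flux_true[1] * 1e9
  res_f <- analyse_recording(sim$recording, ideal_cal(),
                             flux_config("diffusion_gradient", "K+"))
  res_c <- analyse_recording(sim$recording, ideal_cal(),
                             flux_config("chemical_potential", "K+",
                                         use_position1_conc = TRUE))
  # analyser sign convention: efflux (source flux > 0) comes out negative
  for (res in list(res_f, res_c)) {
    got <- res$flux1_nmol_m2_s[2:5]
    expect_true(all(got < 0))
    expect_equal(-got, rep(true_nmol, 4), tolerance = 0.02)
  }
})

test_that("per-loop concentrations alternate between the two positions", {
  sim <- simulate_recording(recovery_scenario(tau = 0, noise_sd = 0))
  res <- analyse_recording(sim$recording, ideal_cal(),
                           flux_config("diffusion_gradient", "K+"))
  expect_equal(res$conc1_mM, sim$truth$conc_at_electrode_mM,
               tolerance = 1e-9)
  expect_equal(res$position_index, sim$truth$position_index)
})

test_that("a full pipeline is invariant to an inverting amplifier", {
  sim <- simulate_recording(recovery_scenario(tau = 0, noise_sd = 0))
  rec <- sim$recording
  gain <- -33
  s2 <- rec$samples
  s2$sise1 <- gain * s2$sise1
  rec_g <- recording(s2, rec$meta)
  conc <- c(0.1, 1, 10)
  cal <- fit_calibration(conc, 58 * log10(conc))
  cal_g <- fit_calibration(conc, gain * 58 * log10(conc))
  for (cfg in list(flux_config("chemical_potential", "K+", bath_conc = 0.5),
                   flux_config("diffusion_gradient", "K+"))) {
    f1 <- analyse_recording(rec, cal, cfg)$flux1_nmol_m2_s
    f2 <- analyse_recording(rec_g, cal_g, cfg)$flux1_nmol_m2_s
    expect_equal(f1, f2, tolerance = 1e-9)
  }
})

test_that("event marks merge into the analysis rows by time", {
  sc <- simulation_scenario(n_loops = 4, electrode = list(noise_sd = 0))
  rec0 <- simulate_recording(sc)$recording
  rec <- recording(rec0$samples, rec0$meta,
                   events = data.frame(time = c(12, 14), text = c("a", "b")))
  res <- analyse_recording(rec, ideal_cal(),
                           flux_config("diffusion_gradient", "K+"))
  expect_equal(res$event_mark, c("", "a; b", "", ""))
})

test_that("analysing a sise2 recording without its calibration fails", {
  acq <- acquisition_config(sise2 = TRUE)
  sc <- simulation_scenario(acquisition = acq, n_loops = 3,
                            electrode = list(noise_sd = 0))
  rec <- simulate_recording(sc)$recording
  expect_error(analyse_recording(rec, ideal_cal(),
                                 flux_config("diffusion_gradient", "K+")),
               "cal2")
})

test_that("start_fit can be changed at re-analysis without touching the data", {
  sim <- simulate_recording(recovery_scenario(tau = 0, noise_sd = 0))
  before <- sim$recording$samples
  r5 <- analyse_recording(sim$recording, ideal_cal(),
                          flux_config("diffusion_gradient", "K+"),
                          start_fit = 5)
  r8 <- analyse_recording(sim$recording, ideal_cal(),
                          flux_config("diffusion_gradient", "K+"),
                          start_fit = 8)
  expect_identical(sim$recording$samples, before)
  # noise-free, instant electrode: estimates identical whatever the window
  expect_equal(r5$flux1_nmol_m2_s, r8$flux1_nmol_m2_s, tolerance = 1e-9)
})

write_scenario_yaml <- function(path, n_loops = 5, noise_sd = 0, seed = 1,
                                flux_nmol = 200) {
  writeLines(c(
    "ion: K+",
    "bulk_conc_mM: 0.5",
    sprintf("true_flux_nmol_m2_s: %g", flux_nmol),
    "electrode: {slope_mV_per_decade: 58, intercept_mV: 0, tau_s: 0.3,",
    sprintf("  drift_mV_min: 0.5, noise_sd_mV: %g}", noise_sd),
    "geometry: {shape: flat, gap0_um: 50}",
    sprintf("n_loops: %d", n_loops),
    sprintf("seed: %d", seed)), path)
}

write_analysis_yaml <- function(path, method = "diffusion_gradient") {
  writeLines(c(
    sprintf("method: %s", method),
    "ion: K+",
    "bath_conc_mM: 0.5",
    "geometry: {shape: flat, gap0_um: 50}",
    "start_fit_s: 5"), path)
}

test_that("command-line simulate/analyse round trip recovers the flux", {
  dir <- withr::local_tempdir()
  scen <- file.path(dir, "scenario.yaml")
  write_scenario_yaml(scen)
  out <- file.path(dir, "run1")
  suppressMessages(sise_cli(c("simulate", "--scenario", scen,
                              "--out", out)))
  expect_true(file.exists(paste0(out, "_recording.tsv")))
  expect_true(file.exists(paste0(out, "_truth.tsv")))
  manifest <- jsonlite::read_json(paste0(out, "_manifest.json"))
  expect_equal(manifest$command, "simulate")
  expect_equal(manifest$seed, 1)

  caltab <- file.path(dir, "cal.tsv")
  writeLines(c("conc_mM\tvoltage_mV", "0.1\t-58", "1\t0", "10\t58"), caltab)
  cfg <- file.path(dir, "analysis.yaml")
  write_analysis_yaml(cfg)
  outfile <- file.path(dir, "analysis.tsv")
  suppressMessages(sise_cli(c("analyse", "--recording",
                              paste0(out, "_recording.tsv"),
                              "--config", cfg, "--cal", caltab,
                              "--out", outfile)))
  res <- utils::read.delim(outfile)
  expect_equal(nrow(res), 5)
  truth <- utils::read.delim(paste0(out, "_truth.tsv"))
  expect_equal(mean(-res$flux1_nmol_m2_s, na.rm = TRUE),
               truth$flux_true[1] * 1e9, tolerance = 0.02)
})

test_that("repeated seeded simulation is file-identical", {
  dir <- withr::local_tempdir()
  scen <- file.path(dir, "scenario.yaml")
  write_scenario_yaml(scen, noise_sd = 0.05)
  for (run in c("a", "b")) {
    suppressMessages(sise_cli(c("simulate", "--scenario", scen, "--out",
                                file.path(dir, run), "--seed", "7")))
  }
  fa <- file.path(dir, "a_recording.tsv")
  fb <- file.path(dir, "b_recording.tsv")
  expect_identical(readBin(fa, "raw", file.size(fa)),
                   readBin(fb, "raw", file.size(fb)))
  # a different seed changes the noise
  suppressMessages(sise_cli(c("simulate", "--scenario", scen, "--out",
                              file.path(dir, "c"), "--seed", "8")))
  fc <- file.path(dir, "c_recording.tsv")
  expect_false(identical(readBin(fb, "raw", file.size(fb)),
                         readBin(fc, "raw", file.size(fc))))
})

test_that("calibrate subcommand reports the fit and flags poor electrodes", {
  dir <- withr::local_tempdir()
  good <- file.path(dir, "good.tsv")
  writeLines(c("conc_mM\tvoltage_mV", "0.1\t-58", "1\t0", "10\t58"), good)
  expect_output(expect_no_warning(sise_cli(c("calibrate", "--table", good))),
                "slope:\\s+58")
  bad <- file.path(dir, "bad.tsv")
  writeLines(c("conc_mM\tvoltage_mV", "0.1\t-40", "1\t0", "10\t40"), bad)
  expect_warning(capture.output(sise_cli(c("calibrate", "--table", bad))),
                 "20%")
  one <- file.path(dir, "one.tsv")
  writeLines(c("conc_mM\tvoltage_mV", "1\t5"), one)
  expect_error(suppressWarnings(capture.output(
    sise_cli(c("calibrate", "--table", one)))), "distinct")
})

test_that("cli validates scenarios and unknown commands", {
  dir <- withr::local_tempdir()
  scen <- file.path(dir, "bad.yaml")
  writeLines(c("ion: K+", "bulk_conc_mM: -1"), scen)
  expect_error(sise_cli(c("simulate", "--scenario", scen, "--out",
                          file.path(dir, "x"))), "bulk_conc")
  expect_error(sise_cli(c("frobnicate")), "unknown subcommand")
  expect_error(sise_cli(c("simulate")), "--scenario")
})
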