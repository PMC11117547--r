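test_that("configuration invariants are enforced", {
  expect_error(sim_config(mixing = matrix(1, 2, 2)), "n_channels x n_channels")
  bad_diag <- matrix(c(0.9, 0, 0, 0, 1, 0, 0, 0, 1), 3)
  expect_error(sim_config(mixing = bad_diag), "diagonal")
  bad_off <- diag(3); bad_off[1, 2] <- 1.5
  expect_error(sim_config(mixing = bad_off), "off-diagonal")
  expect_error(sim_config(mmg_band = c(5, 600)), "fs/2")
  expect_error(sim_config(duration = 0.0005, fs = 1000), "positive integer")
  expect_error(sim_config(act_range = c(0.6, 0.2)), "act_range")
})

test_that("generated recordings have the configured shape and are deterministic", {
  cfg <- sim_config(duration = 1, seed = 5)
  rec <- generate_recording(cfg)
  expect_s3_class(rec, "mmg_recording")
  expect_length(rec$force, 1000)
  expect_true(all(vapply(rec$channels, length, integer(1)) == 1000))
  expect_identical(names(rec$channels), c("RF", "VL", "VM"))

  rec2 <- generate_recording(cfg)
  expect_identical(rec$channels, rec2$channels)
  expect_identical(rec$force, rec2$force)
})

test_that("force stays within the activation range up to noise and filter slack", {
  cfg <- sim_config(duration = 8, seed = 3)
  rec <- generate_recording(cfg)
  lo <- cfg$act_range[1]; hi <- cfg$act_range[2]
  slack <- 3 * cfg$force_noise_sd * (hi - lo) + 0.01
  expect_true(all(rec$force >= lo - slack))
  expect_true(all(rec$force <= hi + slack))
  # force targets strictly positive so MAPE is defined
  expect_true(all(rec$force > 0))
})

test_that("identity mixing without sensor noise yields the pure sources", {
  # with no mixing and no noise the channels are the latent sources, which
  # are mutually independent: every pair classifies as low cross-talk in
  # most seeds (8 s analysis segment: band-limited signals need a few
  # hundred effective samples before the spurious-peak floor drops)
  low <- vapply(1:5, function(s) {
    cfg_s <- sim_config(duration = 8, seed = s, mixing = diag(3),
                        sensor_noise_sd = 0)
    ct <- pairwise_crosstalk(denoise_recording(generate_recording(cfg_s)),
                             segment = c(0, 8))
    all(ct$pccc < 0.30)
  }, logical(1))
  expect_gte(sum(low), 4)
})

test_that("fully shared source weights give near-identical channels", {
  mix <- matrix(c(1, 1, 0, 1, 1, 0, 0, 0, 1), 3, byrow = TRUE)
  cfg <- sim_config(duration = 4, seed = 7, mixing = mix,
                    wander_frac = rep(0, 3), sensor_noise_sd = 0)
  rec <- generate_recording(cfg)
  ct <- pairwise_crosstalk(rec)
  expect_gt(ct$pccc[ct$pair == "MP1"], 0.95)
})

test_that("datasets derive independent, reproducible trials", {
  cfg <- sim_config(duration = 1, seed = 1)
  trials <- generate_dataset(cfg, 3)
  expect_length(trials, 3)
  expect_false(identical(trials[[1]]$channels$RF, trials[[2]]$channels$RF))
  expect_false(identical(trials[[2]]$channels$RF, trials[[3]]$channels$RF))

  # singleton dataset equals a direct generation at the derived seed
  one <- generate_dataset(cfg, 1)
  cfg1 <- cfg; cfg1$seed <- mmgforce:::derive_seed(cfg$seed, 1001)
  expect_identical(one[[1]]$force, generate_recording(cfg1)$force)

  # full determinism of the dataset
  expect_identical(lapply(generate_dataset(cfg, 2), `[[`, "force"),
                   lapply(generate_dataset(cfg, 2), `[[`, "force"))
  expect_error(generate_dataset(cfg, 0), "n_trials")
})

test_that("CSV round trip preserves the recording", {
  rec <- short_recording(4)
  path <- tempfile(fileext = ".csv")
  write_recording_csv(rec, path)
  back <- read_recording_csv(path)
  expect_equal(back$fs, rec$fs, tolerance = 1e-6)
  expect_equal(back$channels$VL, rec$channels$VL, tolerance = 1e-6)
  expect_equal(back$force, rec$force, tolerance = 1e-6)
  unlink(path)
})

test_that("activation profiles cover ramp and plateau shapes", {
  t_ramp <- generate_recording(sim_config(duration = 2, seed = 1,
                                          activation_profile = "ramp"))
  a <- t_ramp$activations[, "VL"]
  expect_true(stats::cor(a, seq_along(a)) > 0.5)
  t_step <- generate_recording(sim_config(duration = 2, seed = 1,
                                          activation_profile = "plateau-steps",
                                          wander_frac = rep(0, 3)))
  expect_lte(length(unique(t_step$activations[, "VL"])), 5)
})
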