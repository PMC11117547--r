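test_that("window arithmetic follows the count formula", {
  spec <- window_spec(250, 50, 1000)
  expect_equal(n_windows(1000, spec), 16)
  expect_equal(n_windows(250, spec), 1)
  expect_error(n_windows(240, spec), "shorter")
  # formula holds across a grid of sizes
  for (len in c(250, 251, 499, 500, 1234)) {
    for (hop in c(1, 50, 250)) {
      sp <- window_spec(250, hop, 1000)
      W <- sliding_windows(seq_len(len), sp)
      expect_equal(nrow(W), floor((len - 250) / hop) + 1)
    }
  }
  W <- sliding_windows(1:300, window_spec(250, 50, 1000))
  expect_equal(W[1, 1:3], 1:3)
  expect_equal(W[2, 1], 51)
  expect_error(window_spec(250, 300), "hop")
})

test_that("simple descriptors match hand computations", {
  expect_equal(unname(extract_features(rep(c(3, -4), 40), fs = 1000)["rms"]),
               sqrt(12.5))
  expect_equal(unname(extract_features(rep(c(1, -1, 1), 30), fs = 1000)["mav"]), 1)
  x <- rep(c(1, -1), 50)
  expect_equal(unname(extract_features(x, fs = 1000)["zc"]), 99)
  # mean frequency of a pure 20 Hz tone
  w <- sin(2 * pi * 20 * (0:249) / 1000)
  expect_equal(unname(extract_features(w, fs = 1000)["mnf"]), 20, tolerance = 2)
  expect_equal(unname(extract_features(w, fs = 1000)["pkf"]), 20, tolerance = 2)
})

test_that("the bank is deterministic, complete and rejects degenerate windows", {
  set.seed(5)
  x <- rnorm(250)
  f1 <- extract_features(x, 1000)
  f2 <- extract_features(x, 1000)
  expect_identical(f1, f2)
  expect_length(f1, 25)
  expect_identical(names(f1), feature_names())
  expect_true(all(is.finite(f1)))
  expect_error(extract_features(rep(1, 250), 1000), "degenerate")
  expect_error(extract_features(rnorm(32), 1000), "64")
})

test_that("features scale as documented", {
  set.seed(6)
  x <- rnorm(256)
  f1 <- extract_features(x, 1000)
  f3 <- extract_features(3 * x, 1000)
  # amplitude features scale linearly
  for (nm in c("mav", "rms", "sd", "wl", "iav")) {
    expect_equal(unname(f3[nm]), 3 * unname(f1[nm]), tolerance = 1e-9)
  }
  expect_equal(unname(f3["var"]), 9 * unname(f1["var"]), tolerance = 1e-9)
  # frequency locations are amplitude-invariant
  for (nm in c("mnf", "mdf", "pkf", "smr", "fsd")) {
    expect_equal(unname(f3[nm]), unname(f1[nm]), tolerance = 1e-9)
  }
  # normalized nonlinear and relative-energy features are amplitude-invariant
  for (nm in c("sampen", "apen", "hfd", "lzc", "dfa",
               "rwe1", "rwe2", "rwe3", "rwe4", "went")) {
    expect_equal(unname(f3[nm]), unname(f1[nm]), tolerance = 1e-8)
  }
})

test_that("entropy estimators agree with the reference implementations", {
  skip_if_not_installed("pracma")
  set.seed(7)
  for (rep in 1:3) {
    x <- rnorm(150)
    r <- 0.2 * sd(x)
    expect_equal(sample_entropy_fast(x, 2, r),
                 pracma::sample_entropy(x, edim = 2, r = r), tolerance = 1e-10)
    expect_equal(approx_entropy_fast(x, 2, r),
                 pracma::approx_entropy(x, edim = 2, r = r), tolerance = 1e-10)
  }
})

test_that("wavelet subband energies approximately conserve total energy", {
  set.seed(8)
  x <- rnorm(256)
  en <- mmgforce:::dwt_energies(x, levels = 4)
  # orthogonal filter bank: subband energies sum to about the signal energy
  # (boundary extension makes this approximate)
  expect_equal(sum(en), sum(x^2), tolerance = 0.15)
  expect_true(all(en > 0))
})

test_that("targets align with windows under each rule", {
  spec <- window_spec(100, 100, 1000)
  force <- rep(0.4, 500)
  expect_equal(align_targets(force, spec), rep(0.4, 5))
  ramp <- seq(0, 1, length.out = 100)
  expect_equal(align_targets(ramp, window_spec(100, 100, 1000)), mean(ramp))
  # non-overlapping windows partition the trace
  y <- align_targets(seq_len(500), spec)
  expect_equal(sum(y * 100), sum(seq_len(500)))
  expect_equal(align_targets(seq_len(500), spec, rule = "last"),
               c(100, 200, 300, 400, 500))
  expect_equal(align_targets(seq_len(500), spec, rule = "center"),
               c(50, 150, 250, 350, 450))
})

test_that("combination tables have the advertised shapes", {
  rec <- short_recording(3)
  spec <- window_spec(250, 250, 1000)
  t2 <- build_feature_table(rec, channels = "F2", spec = spec)
  expect_equal(ncol(t2$X), 25)
  expect_true(all(startsWith(colnames(t2$X), "VL:")))
  t7 <- build_feature_table(rec, channels = "F7", spec = spec)
  expect_equal(ncol(t7$X), 75)
  t4 <- build_feature_table(rec, channels = "F4", spec = spec)
  expect_equal(ncol(t4$X), 50)
  expect_equal(nrow(t7$X), length(t7$target))
  expect_error(build_feature_table(rec, channels = "XX"), "unknown channel")
  expect_identical(feature_combination("F6"), c("VL", "VM"))
  expect_error(feature_combination("F8"), "unknown")

  # column slicing equals direct construction
  sub <- subset_channels(t7, "F2")
  expect_identical(sub$X, t2$X)
  expect_identical(sub$channels, "VL")
})
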