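# Filtering, referencing, segmentation, rejection, and the wavelet/ICA
# ocular-artifact machinery.

test_that("band-pass keeps the passband and attenuates out-of-band tones", {
  fs <- 1000
  mid <- 1001:4000  # avoid filtfilt edge transients
  rms <- function(v) sqrt(mean(v^2))

  s10 <- sine_recording(10, fs, dur = 5)
  f10 <- bandpass_filter(s10)
  expect_equal(rms(f10$data[1, mid]) / rms(s10$data[1, mid]), 1,
               tolerance = 0.05)

  s60 <- sine_recording(60, fs, dur = 5)
  f60 <- bandpass_filter(s60)
  atten_db <- 20 * log10(rms(f60$data[1, mid]) / rms(s60$data[1, mid]))
  expect_lt(atten_db, -20)

  z <- recording(matrix(0, 1, 2000), fs, "ch1")
  expect_equal(bandpass_filter(z)$data, z$data)

  expect_error(bandpass_filter(s10, lo = 0.1, hi = 600), "Nyquist")
})

test_that("filtering and referencing are linear operators", {
  fs <- 250
  set.seed(1)
  x <- recording(matrix(rnorm(3 * 1000), 3), fs, c("a", "b", "c"))
  y <- recording(matrix(rnorm(3 * 1000), 3), fs, c("a", "b", "c"))
  comb <- recording(2 * x$data - 3 * y$data, fs, x$labels)
  for (op in list(function(r) bandpass_filter(r, 1, 40),
                  average_reference)) {
    lhs <- op(comb)$data
    rhs <- 2 * op(x)$data - 3 * op(y)$data
    expect_equal(lhs, rhs, tolerance = 1e-8)
  }
})

test_that("average reference zeroes the instantaneous channel mean", {
  r <- recording(matrix(c(2, 2, 2, 0, 0, 0), 2, byrow = TRUE), 100,
                 c("a", "b"))
  ar <- average_reference(r)
  expect_equal(unname(ar$data[1, ]), c(1, 1, 1))
  expect_equal(unname(ar$data[2, ]), c(-1, -1, -1))

  set.seed(2)
  r2 <- recording(matrix(rnorm(5 * 200), 5), 100, paste0("c", 1:5))
  expect_lt(max(abs(colMeans(average_reference(r2)$data))), 1e-10)

  expect_error(average_reference(recording(matrix(0, 1, 10), 100, "a")),
               "2 channels")
})

test_that("segmentation counts and remainder handling are exact", {
  fs <- 100
  r60 <- recording(matrix(rnorm(2 * 60 * fs), 2), fs, c("a", "b"))
  s <- segment_recording(r60, 3)
  expect_length(s$segments, 20)
  expect_true(all(vapply(s$segments, ncol, integer(1)) == 300))

  r7 <- recording(matrix(rnorm(2 * 7 * fs), 2), fs, c("a", "b"))
  expect_length(segment_recording(r7, 3)$segments, 2)

  r29 <- recording(matrix(rnorm(2 * 290), 2), fs, c("a", "b"))
  expect_error(segment_recording(r29, 3), "shorter than one segment")
})

test_that("amplitude rejection removes exactly the offending segments", {
  fs <- 100
  data <- matrix(0, 2, 900)
  data[1, 450] <- 130  # second segment contains a 130 uV sample
  segs <- segment_recording(recording(data, fs, c("a", "b")), 3)
  kept <- reject_segments(segs, 120)
  expect_length(kept$segments, 2)
  expect_equal(kept$rejected_count, 1L)
  expect_equal(kept$provenance$start_sample, c(1, 601))
  expect_equal(kept$rejected_count + length(kept$segments),
               length(segs$segments))

  # all-zero segments all survive; a tiny threshold kills noise segments
  z <- segment_recording(recording(matrix(0, 1, 600), fs, "a"), 3)
  expect_length(reject_segments(z, 120)$segments, 2)
  nz <- segment_recording(recording(matrix(rnorm(600), 1), fs, "a"), 3)
  expect_length(reject_segments(nz, 1e-4)$segments, 0)
})

test_that("robust sigma matches its Gaussian calibration", {
  expect_equal(robust_sigma(rep(3, 10)), 3 / 0.6745)
  set.seed(3)
  expect_equal(robust_sigma(rnorm(1e5)), 1, tolerance = 0.02)
  expect_equal(robust_sigma(numeric(5)), 0)
  expect_error(robust_sigma(numeric(0)), "non-empty")
})

test_that("coefficient thresholding zeroes only super-threshold entries", {
  expect_equal(threshold_coefficients(c(1, -3, 0.5), 2), c(1, 0, 0.5))
  x <- c(-5, 0, 2, 7)
  expect_equal(threshold_coefficients(x, Inf), x)
  expect_equal(threshold_coefficients(x, 0), c(0, 0, 0, 0))
})

test_that("periodized DWT reconstructs perfectly and preserves energy", {
  for (fam in c("haar", "db2", "db4")) {
    set.seed(4)
    x <- rnorm(512)
    dec <- dwt_periodic(x, fam, levels = 5)
    expect_equal(idwt_periodic(dec), x, tolerance = 1e-10)
    energy <- sum(dec$approx^2) + sum(unlist(dec$details)^2)
    expect_equal(energy, sum(x^2), tolerance = 1e-10)
  }
  expect_error(dwt_periodic(rnorm(100), "db4", 8), "divisible")
})

test_that("wavelet suppression removes transients, spares the background", {
  set.seed(5)
  x <- rnorm(2048)
  spike <- x
  spike[1000:1030] <- spike[1000:1030] + 40
  sup <- wavelet_suppress(spike, wavelet_params(levels = 6))
  # the transient is strongly attenuated...
  expect_lt(max(abs(sup$x[1000:1030])), 20)
  # ...while regions away from it stay close to the original
  expect_gt(cor(sup$x[1:800], spike[1:800]), 0.95)
  expect_gt(sup$n_zeroed, 0)
})

test_that("ICA separates a planted non-Gaussian source", {
  set.seed(6)
  n <- 4000
  src <- rbind(sign(rnorm(n)) * rexp(n), rnorm(n), rnorm(n))
  A <- matrix(rnorm(9), 3)
  X <- A %*% src
  dec <- fast_ica(X, seed = 2)
  expect_true(dec$converged)
  # mixing model reproduces the data
  expect_equal(dec$A %*% dec$S + dec$means, X, tolerance = 1e-6)
  # the heavy-tailed source is recovered by some component
  cors <- abs(cor(t(dec$S), src[1, ]))
  expect_gt(max(cors), 0.95)
})

test_that("ocular artifact suppression cleans frontal power, spares occipital", {
  cfg <- test_config()
  clean <- simulate_recording(cfg, "hc", seed = 3)
  dirty <- inject_ocular_artifacts(clean, rate = 12, amplitude = 150, seed = 4)
  res <- remove_ocular_artifacts(dirty, ica_seed = 1)
  out <- res$recording

  expect_identical(out$fs, dirty$fs)
  expect_identical(out$labels, dirty$labels)
  expect_identical(dim(out$data), dim(dirty$data))
  expect_gt(length(res$report$flagged), 0)

  bandpow <- function(rec, ch, lo, hi) {
    sp <- welch_spectra(rec, window = 2)
    sum(sp$auto[sp$freqs >= lo & sp$freqs <= hi, match(ch, rec$labels)])
  }
  reduction <- 1 - bandpow(out, "FP1", 0.5, 4) / bandpow(dirty, "FP1", 0.5, 4)
  expect_gt(reduction, 0.5)
  expect_gt(cor(out$data["O1", ], dirty$data["O1", ]), 0.9)

  # artifact-free input passes through essentially unchanged
  res0 <- remove_ocular_artifacts(clean, ica_seed = 1)
  cc <- vapply(seq_along(clean$labels), function(i)
    cor(clean$data[i, ], res0$recording$data[i, ]), numeric(1))
  expect_gt(min(cc), 0.95)

  # near-idempotence: a second pass changes little compared with the first
  rms <- function(m) sqrt(mean(m^2))
  ratios <- vapply(1:3, function(s) {
    cl <- simulate_recording(cfg, "hc", seed = s + 10)
    dt <- inject_ocular_artifacts(cl, 12, 150, seed = s + 20)
    r1 <- remove_ocular_artifacts(dt)$recording
    r2 <- remove_ocular_artifacts(r1)$recording
    rms(r2$data - r1$data) / rms(r1$data - dt$data)
  }, numeric(1))
  expect_lt(median(ratios), 0.1)
})
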