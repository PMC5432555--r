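test_that("segmentation yields the advertised geometry and zero maps to zero", {
  rec <- list(data = matrix(0, 3, 150000), fs = 500)
  S <- segment_fft(rec)
  expect_identical(dim(S$coef), c(3L, 300L, 251L))
  expect_identical(S$delta_f, 1)
  expect_true(all(S$coef == 0))
  # trailing partial segment discarded
  rec2 <- list(data = matrix(rnorm(3 * 1250), 3, 1250), fs = 500)
  expect_identical(dim(segment_fft(rec2)$coef)[2], 2L)
  expect_error(segment_fft(list(data = matrix(0, 2, 600), fs = 500)),
               "two segments")
})

test_that("windowed coefficients equal the direct DFT sum, on both code paths", {
  fs <- 500
  tt <- seq_len(5 * fs) - 1
  x <- cos(2 * pi * 10 * tt / fs)
  rec <- list(data = rbind(x, 0.3 * x), fs = fs)
  S_full <- segment_fft(rec)
  S_sel <- segment_fft(rec, freqs = c(6, 10, 16))
  for (l in 1:5) {
    seg <- x[((l - 1) * fs + 1):(l * fs)]
    ref10 <- direct_windowed_dft(seg, 10)
    expect_lt(Mod(S_full$coef[1, l, 11] - ref10), 1e-9 * Mod(ref10))
    expect_lt(Mod(S_sel$coef[1, l, 2] - ref10), 1e-9 * Mod(ref10))
  }
  expect_equal(S_sel$coef, S_full$coef[, , c(7, 11, 17)], tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_error(segment_fft(rec, freqs = 10.5), "grid")
})

test_that("auto-bispectrum reproduces perfect coupling and the random-phase null", {
  # constant amplitudes, phases with phi1 + phi2 - phi3 = 0 per segment
  set.seed(301)
  L <- 500
  p1 <- runif(L, 0, 2 * pi); p2 <- runif(L, 0, 2 * pi)
  co <- array(0i, c(1, L, 3))
  co[1, , 1] <- exp(1i * p1)
  co[1, , 2] <- exp(1i * p2)
  co[1, , 3] <- exp(1i * (p1 + p2))
  S <- make_segments(co, freqs = c(6, 10, 16))
  B <- auto_bispectrum(S, 1, 6, 10)
  expect_equal(B, 1 + 0i, tolerance = 1e-12)
  # random third phase: Monte-Carlo null level
  L2 <- 10000
  co2 <- array(exp(1i * runif(3 * L2, 0, 2 * pi)), c(1, L2, 3))
  S2 <- make_segments(co2, freqs = c(6, 10, 16))
  expect_lt(abs(auto_bispectrum(S2, 1, 6, 10)), 0.05)
  # zero signal
  S0 <- make_segments(array(0i, c(1, 4, 3)), freqs = c(6, 10, 16))
  expect_identical(auto_bispectrum(S0, 1, 6, 10), 0i)
  expect_error(auto_bispectrum(S, 1, 6, 11), "grid")
})

test_that("three-norm matches hand arithmetic and degenerate cases", {
  co <- array(0i, c(1, 2, 3))
  co[1, , 1] <- c(1, 2)          # |v| = (1, 2), L = 2
  S <- make_segments(co, freqs = c(6, 10, 16))
  expect_equal(three_norm(S, 1, 6), 4.5^(1 / 3), tolerance = 1e-12)
  expect_identical(three_norm(S, 1, 10), 0)
  # constant modulus c gives Q = c
  co[1, , 2] <- 0.7 * exp(1i * c(0.3, 2.2))
  S <- make_segments(co, freqs = c(6, 10, 16))
  expect_equal(three_norm(S, 1, 10), 0.7, tolerance = 1e-12)
})

test_that("bicoherence attains the Hoelder bound, is scale invariant and null-calibrated", {
  set.seed(302)
  L <- 300
  p1 <- runif(L, 0, 2 * pi); p2 <- runif(L, 0, 2 * pi)
  co <- array(0i, c(2, L, 3))
  co[1, , 1] <- exp(1i * p1); co[1, , 2] <- exp(1i * p2)
  co[1, , 3] <- exp(1i * (p1 + p2))
  co[2, , ] <- co[1, , ] * 3.7          # rescaled copy
  S <- make_segments(co, freqs = c(6, 10, 16))
  expect_equal(abs(bicoherence(S, 1, 6, 10)), 1, tolerance = 1e-12)
  expect_equal(bicoherence(S, 2, 6, 10), bicoherence(S, 1, 6, 10),
               tolerance = 1e-12)
  # independent Gaussian bins: observed |b| below the shuffled-segment null
  g <- array(complex(real = rnorm(L * 3), imaginary = rnorm(L * 3)),
             c(1, L, 3))
  Sg <- make_segments(g, freqs = c(6, 10, 16))
  b_obs <- abs(bicoherence(Sg, 1, 6, 10))
  null <- replicate(300, {
    Sh <- Sg
    Sh$coef[1, , 2] <- Sg$coef[1, sample(L), 2]
    abs(bicoherence(Sh, 1, 6, 10))
  })
  expect_lt(b_obs, quantile(null, 0.99))
  # degenerate all-zero bin: defined as 0 with a warning
  z <- make_segments(array(0i, c(1, 5, 3)), freqs = c(6, 10, 16))
  expect_warning(bz <- bicoherence(z, 1, 6, 10), "zero normalization")
  expect_identical(bz, 0i)
})

test_that("cross-bicoherence reduces to bicoherence and detects simulated coupling", {
  set.seed(303)
  L <- 200
  co <- array(complex(real = rnorm(3 * L * 3), imaginary = rnorm(3 * L * 3)),
              c(3, L, 3))
  co[2, , ] <- co[1, , ]                 # exact copies of channel 1
  co[3, , ] <- co[1, , ]
  S <- make_segments(co, freqs = c(6, 10, 16))
  expect_equal(cross_bicoherence(S, 1, 1, 1, 6, 10), bicoherence(S, 1, 6, 10),
               tolerance = 1e-14)
  expect_equal(cross_bicoherence(S, 1, 2, 3, 6, 10), bicoherence(S, 1, 6, 10),
               tolerance = 1e-14)
  # coupled-pair simulation: triplet coupling beats the segment-shuffle null
  m <- test_model()
  lay <- make_layout(21, m)
  grid <- get_cached("grid5mm", function() source_grid(m, 0.005))
  rec <- gen_dataset(test_cfg(duration = 120, seed = 41), lay, m, grid = grid)
  Ssim <- segment_fft(rec, freqs = c(6, 10, 16))
  cb_obs <- abs(cross_bicoherence(Ssim, 1, 5, 9, 6, 10))
  Lsim <- dim(Ssim$coef)[2]
  null <- replicate(200, {
    Sh <- Ssim
    Sh$coef[, , 2] <- Ssim$coef[, sample(Lsim), 2]
    abs(cross_bicoherence(Sh, 1, 5, 9, 6, 10))
  })
  expect_gt(cb_obs, quantile(null, 0.99))
})

test_that("antisymmetric cross-bicoherence is antisymmetric and kills single-source mixtures", {
  set.seed(304)
  L <- 150
  co <- array(complex(real = rnorm(4 * L * 3), imaginary = rnorm(4 * L * 3)),
              c(4, L, 3))
  S <- make_segments(co, freqs = c(6, 10, 16))
  expect_identical(antisym_cross_bicoherence(S, 2, 3, 2, 6, 10), 0i)
  a123 <- antisym_cross_bicoherence(S, 1, 2, 3, 6, 10)
  a321 <- antisym_cross_bicoherence(S, 3, 2, 1, 6, 10)
  expect_identical(a123, -a321)
  # channels as instantaneous mixtures of a single source
  u <- matrix(complex(real = rnorm(L * 3), imaginary = rnorm(L * 3)), L, 3)
  w <- c(0.3, -1.2, 2.5, 0.7)
  mix <- array(0i, c(4, L, 3))
  for (f in 1:3) mix[, , f] <- outer(w, u[, f])
  Smix <- make_segments(mix, freqs = c(6, 10, 16))
  for (tri in list(c(1, 2, 3), c(4, 2, 1), c(2, 3, 4)))
    expect_lt(abs(antisym_cross_bicoherence(Smix, tri[1], tri[2], tri[3], 6, 10)),
              1e-10)
})

test_that("triplet tensors agree with the naive triple loop and per-triplet calls", {
  set.seed(305)
  n <- 5; L <- 40
  co <- array(complex(real = rnorm(n * L * 3), imaginary = rnorm(n * L * 3)),
              c(n, L, 3))
  S <- make_segments(co, freqs = c(6, 10, 16))
  cb <- triplet_tensor(S, 6, 10, "cb")
  acb <- triplet_tensor(S, 6, 10, "acb")
  Bn <- naive_cross_bispectrum(co[, , 1], co[, , 2], co[, , 3])
  Q <- function(f) vapply(1:n, function(i) three_norm(S, i, c(6, 10, 16)[f]),
                          numeric(1))
  Nn <- outer(outer(Q(1), Q(2)), Q(3))
  expect_lt(max(abs(cb - Bn / Nn)), 1e-12)
  for (tri in list(c(1, 2, 3), c(5, 4, 1), c(2, 2, 2))) {
    expect_equal(cb[tri[1], tri[2], tri[3]],
                 cross_bicoherence(S, tri[1], tri[2], tri[3], 6, 10),
                 tolerance = 1e-13)
    expect_equal(acb[tri[1], tri[2], tri[3]],
                 antisym_cross_bicoherence(S, tri[1], tri[2], tri[3], 6, 10),
                 tolerance = 1e-13)
  }
  # normalization bound over every tested entry
  expect_lt(max(abs(cb)), 1 + 1e-12)
  expect_lt(max(abs(acb)), 1 + 1e-12)
})

test_that("seed maps extract the matching entries of the full tensors", {
  set.seed(306)
  n <- 6; L <- 50
  co <- array(complex(real = rnorm(n * L * 3), imaginary = rnorm(n * L * 3)),
              c(n, L, 3))
  S <- make_segments(co, freqs = c(6, 10, 16))
  cbm <- seed_maps(S, "ch2", 6, 10, "cb")
  acbm <- seed_maps(S, "ch2", 6, 10, "acb")
  cb <- triplet_tensor(S, 6, 10, "cb")
  acb <- triplet_tensor(S, 6, 10, "acb")
  expect_equal(unname(cbm), unname(cb[2, 2, ]), tolerance = 1e-13)
  expect_equal(unname(acbm), unname(acb[2, 2, ]), tolerance = 1e-13)
  expect_identical(acbm[["ch2"]], 0i)
  expect_equal(cbm[["ch2"]], bicoherence(S, 2, 6, 10), tolerance = 1e-13)
  expect_error(seed_maps(S, "nope", 6, 10), "unknown channel")
})

test_that("the bicoherence scan enumerates the expected grid and finds the coupled pair", {
  # combinatorial count for integer frequencies with f1 + f2 <= 40
  m <- test_model()
  lay <- make_layout(21, m)
  grid <- get_cached("grid5mm", function() source_grid(m, 0.005))
  rec <- gen_dataset(test_cfg(duration = 120, seed = 43), lay, m, grid = grid)
  S <- segment_fft(rec)
  ch <- which.max(abs(bicoherence_channels(S, 6, 10)))
  sc <- bicoherence_scan(S, ch, 40)
  n_expected <- sum(vapply(1:39, function(f1) length(seq(1, 40 - f1)), 1L))
  expect_identical(nrow(sc$table), n_expected)
  expect_true(all(sc$table$f1 + sc$table$f2 <= 40))
  expect_true(sc$peak[["f1"]] + sc$peak[["f2"]] == 16 &&
                sc$peak[["f1"]] %in% c(6, 10))
  expect_error(bicoherence_scan(S, 1, 600), "Nyquist")
})

test_that("b_max applies the first-maximum tie rule", {
  expect_identical(b_max(c(a = 0.2, b = 0.2, c = 0.2))$channel, "a")
  expect_identical(b_max(c(x = 0.4))$value, 0.4)
  set.seed(307)
  v <- runif(30)
  names(v) <- paste0("ch", 1:30)
  expect_identical(b_max(v)$value, max(v))
  expect_identical(b_max(v)$channel, names(v)[which.max(v)])
})

test_that("bicoherence is invariant to channel rescaling but not to re-referencing", {
  m <- test_model()
  lay <- make_layout(21, m)
  grid <- get_cached("grid5mm", function() source_grid(m, 0.005))
  rec <- gen_dataset(test_cfg(duration = 120, seed = 47), lay, m, grid = grid)
  S <- segment_fft(rec, freqs = c(6, 10, 16))
  b0 <- bicoherence_channels(S, 6, 10)
  # rescaling
  rec_scaled <- rec; rec_scaled$data <- rec$data * 1e6
  bs <- bicoherence_channels(segment_fft(rec_scaled, freqs = c(6, 10, 16)), 6, 10)
  expect_equal(bs, b0, tolerance = 1e-12)
  # Cz-referencing changes magnitudes well beyond the estimation noise floor
  Tcz <- make_simple_transform("Cz", lay)
  # the vertex channel itself goes to 0/0 -> 0 (warned elsewhere)
  bc <- suppressWarnings(
    bicoherence_channels(segment_fft(apply_transform(Tcz, rec),
                                     freqs = c(6, 10, 16)), 6, 10))
  expect_gt(max(abs(abs(bc) - abs(b0)), na.rm = TRUE), 0.1)
})
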