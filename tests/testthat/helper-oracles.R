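# Independent oracles and small fixture builders used across the suite.

# Closed-form surface potential of a current dipole inside a homogeneous
# conducting sphere with insulating boundary, obtained by summing the
# Legendre series analytically with generating-function identities:
#   sum (2n+1) t^n P_n(x)       = 2 t (x - t)/Rh^3 + 1/Rh - 1
#   sum (2n+1)/n t^n P_n'(x)    = 2 t / Rh^3 + t (1 + Rh)/(Rh (1 - t x + Rh))
# with Rh = sqrt(1 - 2 t x + t^2).  Independent of the package's truncated
# per-degree transfer-matrix solution.
oracle_homog_sphere <- function(epos, dpos, q, R, sigma) {
  b <- sqrt(sum(dpos^2)); tt <- b / R
  bhat <- dpos / b
  vapply(seq_len(nrow(epos)), function(i) {
    e <- epos[i, ]
    ehat <- e / sqrt(sum(e^2))
    x <- sum(ehat * bhat)
    Rh <- sqrt(1 - 2 * tt * x + tt^2)
    S1 <- 2 * tt * (x - tt) / Rh^3 + 1 / Rh - 1
    S2 <- 2 * tt / Rh^3 + tt * (1 + Rh) / (Rh * (1 - tt * x + Rh))
    qr <- sum(q * bhat)
    qt <- sum(q * ehat) - x * qr
    (qr * S1 / tt + qt * S2 / tt) / (4 * pi * sigma * R^2)
  }, numeric(1))
}

# quasi-uniform points on the full sphere (Fibonacci lattice)
fibonacci_sphere <- function(n, radius = 1) {
  k <- seq_len(n)
  z <- 1 - (2 * k - 1) / n
  th <- acos(z)
  az <- k * pi * (3 - sqrt(5))
  cbind(radius * sin(th) * cos(az), radius * sin(th) * sin(az), radius * z)
}

# dense whole-sphere covering posing as an electrode layout (REST recovery
# is well-posed only with near-complete scalp coverage)
whole_sphere_layout <- function(n, model) {
  pos <- fibonacci_sphere(n, model$radii[3])
  pos <- sweep(pos, 2, model$center, "+")
  lst <- list(names = paste0("S", seq_len(n)), positions = pos,
              mastoid_pair = c("S1", "S2"), vertex = "S1",
              density_tag = NA_integer_, radius = model$radii[3],
              center = model$center)
  class(lst) <- "electrode_layout"
  lst
}

# hand-rolled spectral_segments object from a complex coefficient array
# [channels x segments x bins] at the given bin frequencies
make_segments <- function(coef, freqs, fs = length(freqs) * 2, labels = NULL) {
  if (is.null(labels)) labels <- paste0("ch", seq_len(dim(coef)[1]))
  dimnames(coef) <- list(labels, NULL, NULL)
  structure(list(coef = coef, freqs = freqs, fs = fs, delta_f = 1,
                 segment_length = fs, window = "hanning", labels = labels),
            class = "spectral_segments")
}

# naive O(N^3 L) triple-loop cross-bispectrum, the contract oracle for the
# outer-product accumulation
naive_cross_bispectrum <- function(V1, V2, V3) {
  n <- nrow(V1); L <- ncol(V1)
  B <- array(0i, c(n, n, n))
  for (i in seq_len(n)) for (j in seq_len(n)) for (k in seq_len(n)) {
    acc <- 0i
    for (l in seq_len(L)) acc <- acc + V1[i, l] * V2[j, l] * Conj(V3[k, l])
    B[i, j, k] <- acc / L
  }
  B
}

# direct windowed DFT of one segment at one integer bin
direct_windowed_dft <- function(x, k) {
  n <- length(x)
  w <- signal::hanning(n)
  sum(x * w * exp(-2i * pi * k * (seq_len(n) - 1) / n))
}

# a small fast simulation config for tests
test_cfg <- function(duration = 30, seed = 11, ...) {
  sim_config(duration = duration, seed = seed, ...)
}

test_model <- function() head_model()

# cached small objects shared across test files
.test_env <- new.env()
get_cached <- function(key, builder) {
  if (is.null(.test_env[[key]])) .test_env[[key]] <- builder()
  .test_env[[key]]
}
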