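#' Simulation configuration
#'
#' Parameters of the forward-modelled EEG simulation: two time-delayed
#' quadratically phase-coupled dipole sources whose oscillators are centered
#' at `f1`, `f2` and `f3 = f1 + f2`, plus `n_noise` broadband noise dipoles,
#' projected to the scalp at signal-to-noise ratio `snr` with a small amount
#' of white sensor noise.
#'
#' @param fs sampling rate, Hz.
#' @param duration recording length, s.
#' @param f1,f2,f3 oscillator center frequencies, Hz; `f3` must equal
#'   `f1 + f2`.
#' @param tau coupling delay, s; `tau * fs` must be an integer number of
#'   samples.
#' @param n_noise number of broadband noise dipoles.
#' @param snr ratio of mean channel variance of the coupled-source signals
#'   to that of the noise-source signals.
#' @param filter_bandwidth band-pass width for the oscillators, Hz.
#' @param noise_band band limits of the noise sources, Hz.
#' @param sensor_noise_fraction per-channel white-noise standard deviation
#'   as a fraction of the RMS of the pre-noise sensor signal.
#' @param seed integer seed; fully determines the dataset.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(fs = 500, duration = 300, f1 = 6, f2 = 10, f3 = f1 + f2,
                       tau = 0.010, n_noise = 4, snr = 1.0,
                       filter_bandwidth = 1, noise_band = c(0.5, 100),
                       sensor_noise_fraction = 0.01, seed = NULL) {
  if (abs(f3 - (f1 + f2)) > 1e-9) stop("f3 must equal f1 + f2")
  if (fs <= 2 * max(noise_band)) stop("fs must exceed twice the noise band upper edge")
  if (abs(tau * fs - round(tau * fs)) > 1e-9)
    stop("tau * fs must be an integer number of samples")
  if (snr <= 0) stop("snr must be > 0")
  if (n_noise < 0) stop("n_noise must be >= 0")
  if (duration <= 0 || filter_bandwidth <= 0) stop("invalid configuration")
  structure(list(fs = fs, duration = duration, f1 = f1, f2 = f2, f3 = f3,
                 tau = tau, n_noise = as.integer(n_noise), snr = snr,
                 filter_bandwidth = filter_bandwidth, noise_band = noise_band,
                 sensor_noise_fraction = sensor_noise_fraction, seed = seed),
            class = "sim_config")
}

# zero-phase band-pass: order-3 Butterworth run forward and reverse
bandpass <- function(x, lo, hi, fs, order = 3) {
  bf <- signal::butter(order, c(lo, hi) / (fs / 2), type = "pass")
  signal::filtfilt(bf, x)
}

standardize <- function(x) x / stats::sd(x)

circshift <- function(x, d) {
  n <- length(x)
  d <- d %% n
  if (d == 0) return(x)
  c(x[(n - d + 1):n], x[1:(n - d)])
}

# draws from the current RNG stream
gen_coupled_pair_impl <- function(cfg) {
  M <- round(cfg$fs * cfg$duration)
  hw <- cfg$filter_bandwidth / 2
  x1 <- standardize(bandpass(stats::rnorm(M), cfg$f1 - hw, cfg$f1 + hw, cfg$fs))
  x2 <- standardize(bandpass(stats::rnorm(M), cfg$f2 - hw, cfg$f2 + hw, cfg$fs))
  x3 <- standardize(bandpass(x1 * x2, cfg$f3 - hw, cfg$f3 + hw, cfg$fs))
  s1 <- x1 + x2 + x3
  s2 <- circshift(s1, round(cfg$tau * cfg$fs))
  rbind(s1, s2)
}

#' Quadratically phase-coupled source pair
#'
#' `s1` is the sum of three unit-variance oscillators: white Gaussian noise
#' band-passed around `f1` and `f2` (zero-phase Butterworth), and their
#' pointwise product band-passed around `f3 = f1 + f2`.  `s2` is `s1`
#' delayed circularly by `round(tau * fs)` samples.
#'
#' @param cfg a [sim_config()]; if `cfg$seed` is set the RNG is seeded.
#' @return A 2 x M matrix with rows `s1`, `s2`.
#' @export
gen_coupled_pair <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  gen_coupled_pair_impl(cfg)
}

gen_noise_sources_impl <- function(cfg) {
  M <- round(cfg$fs * cfg$duration)
  if (cfg$n_noise == 0) return(matrix(0, 0, M))
  t(sapply(seq_len(cfg$n_noise), function(i)
    standardize(bandpass(stats::rnorm(M), cfg$noise_band[1], cfg$noise_band[2], cfg$fs))))
}

#' Broadband noise sources
#'
#' Mutually independent white Gaussian processes, zero-phase band-pass
#' filtered to `cfg$noise_band` and standardized to unit variance.
#'
#' @inheritParams gen_coupled_pair
#' @return An `n_noise` x M matrix (0 rows if `n_noise = 0`).
#' @export
gen_noise_sources <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  gen_noise_sources_impl(cfg)
}

#' Multichannel EEG recording
#'
#' @param data numeric matrix [channels x samples], volts.
#' @param fs sampling rate, Hz.
#' @param layout an [electrode_layout()] with one entry per data row.
#' @param reference one of `"INF"`, `"Cz"`, `"DLM"`, `"AVE"`, `"REST"`.
#' @param provenance free-form list (config, seed, transform descriptors).
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, fs, layout, reference = "INF", provenance = list()) {
  data <- as.matrix(data)
  if (!all(is.finite(data))) stop("all samples must be finite")
  if (nrow(data) != length(layout$names))
    stop("data must have one row per layout channel")
  reference <- match.arg(reference, c("INF", "Cz", "DLM", "AVE", "REST"))
  rownames(data) <- layout$names
  structure(list(data = data, fs = fs, layout = layout, reference = reference,
                 provenance = provenance),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("EEG recording: %d channels x %d samples at %g Hz, reference %s\n",
              nrow(x$data), ncol(x$data), x$fs, x$reference))
  invisible(x)
}

# seconds of filtered signal dropped at the start to shed filter/wrap edges
EDGE_TRIM_S <- 2

#' Generate a forward-modelled infinity-referenced dataset
#'
#' Draws 2 coupled and `cfg$n_noise` noise dipoles uniformly at random from
#' the 5 mm source grid with uniformly random unit orientations, projects
#' the source time courses through the infinity-referenced lead field,
#' rescales the noise-source contribution so that the mean-channel-variance
#' ratio equals `cfg$snr`, and adds white sensor noise with standard
#' deviation `cfg$sensor_noise_fraction` times the RMS of the pre-noise
#' signal.  Two extra seconds are simulated and discarded at the start so
#' the delivered recording is free of filter edge effects.
#'
#' @param cfg a [sim_config()]; `cfg$seed` fully determines the output.
#' @param layout an [electrode_layout()].
#' @param model a [head_model()].
#' @param grid optional precomputed [source_grid()] for `model` (5 mm step
#'   used when omitted).
#' @return An [eeg_recording()] with `reference = "INF"`.
#' @export
gen_dataset <- function(cfg, layout, model, grid = NULL) {
  stopifnot(inherits(cfg, "sim_config"), inherits(layout, "electrode_layout"),
            inherits(model, "head_model"))
  if (abs(layout$radius - model$radii[3]) > 1e-6 * model$radii[3])
    stop("layout scalp radius does not match the head model")
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  if (is.null(grid)) grid <- source_grid(model, 0.005)

  n_src <- 2L + cfg$n_noise
  idx <- sample.int(nrow(grid$positions), n_src, replace = FALSE)
  ori <- matrix(stats::rnorm(3 * n_src), n_src, 3)
  ori <- ori / sqrt(rowSums(ori^2))
  dip_c <- dipole_set(grid$positions[idx[1:2], , drop = FALSE],
                      ori[1:2, , drop = FALSE], role = "coupled", model = model)
  L_c <- leadfield(dip_c, layout, model)

  cfg_ext <- cfg
  cfg_ext$duration <- cfg$duration + EDGE_TRIM_S
  keep <- (round(EDGE_TRIM_S * cfg$fs) + 1):round((cfg$duration + EDGE_TRIM_S) * cfg$fs)
  S <- gen_coupled_pair_impl(cfg_ext)
  sig <- (L_c %*% S)[, keep, drop = FALSE]

  v_sig <- mean(apply(sig, 1, stats::var))
  if (cfg$n_noise > 0) {
    dip_n <- dipole_set(grid$positions[idx[-(1:2)], , drop = FALSE],
                        ori[-(1:2), , drop = FALSE], role = "noise", model = model)
    L_n <- leadfield(dip_n, layout, model)
    noi <- (L_n %*% gen_noise_sources_impl(cfg_ext))[, keep, drop = FALSE]
    alpha <- sqrt(v_sig / (cfg$snr * mean(apply(noi, 1, stats::var))))
    noi <- alpha * noi
    v_noi <- mean(apply(noi, 1, stats::var))
    pre <- sig + noi
  } else {
    v_noi <- 0
    pre <- sig
  }
  sd_sens <- cfg$sensor_noise_fraction * sqrt(mean(pre^2))
  data <- pre + matrix(stats::rnorm(length(pre), sd = sd_sens), nrow(pre), ncol(pre))
  eeg_recording(data, cfg$fs, layout, reference = "INF",
                provenance = list(config = cfg, seed = cfg$seed,
                                  source_index = idx, orientations = ori,
                                  achieved_snr = if (v_noi > 0) v_sig / v_noi else Inf,
                                  variance_parts = c(coupled = v_sig,
                                                     noise = v_noi,
                                                     sensor = sd_sens^2)))
}

#' Generate a synthetic multi-subject group
#'
#' Independent per-subject datasets with a shared layout; per-subject seeds
#' are drawn from the RNG seeded by `master_seed`.  Serves as the synthetic
#' stand-in for a multi-subject resting-state study when exercising the
#' group statistics.
#'
#' @param n_subjects number of subjects (>= 2).
#' @param cfg_template a [sim_config()]; its seed field is overwritten per
#'   subject.
#' @param layout an [electrode_layout()].
#' @param model a [head_model()].
#' @param master_seed integer master seed.
#' @param grid optional precomputed [source_grid()].
#' @return List of [eeg_recording()]s, length `n_subjects`.
#' @export
gen_group <- function(n_subjects, cfg_template, layout, model,
                      master_seed = 1L, grid = NULL) {
  if (n_subjects < 2) stop("n_subjects must be >= 2")
  set.seed(master_seed)
  seeds <- sample.int(.Machine$integer.max, n_subjects)
  if (is.null(grid)) grid <- source_grid(model, 0.005)
  lapply(seq_len(n_subjects), function(s) {
    cfg <- cfg_template
    cfg$seed <- seeds[s]
    gen_dataset(cfg, layout, model, grid = grid)
  })
}
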