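#' Segmented windowed Fourier coefficients
#'
#' Divides a recording into non-overlapping segments, applies a Hann window
#' per segment per channel, and evaluates Fourier coefficients.  With
#' `freqs = NULL` the full one-sided FFT spectrum is returned; with a
#' numeric `freqs` only those bins are evaluated by direct windowed DFT
#' sums (identical values, much cheaper when only a few bins are needed).
#' A trailing partial segment is discarded.
#'
#' @param recording an [eeg_recording()] (or any list with `data` [N x M]
#'   and `fs`).
#' @param segment_seconds segment length in seconds (default 1, giving a
#'   frequency resolution of 1 Hz).
#' @param freqs optional frequencies (Hz) to evaluate; each must sit on the
#'   segment frequency grid.
#' @return An object of class `spectral_segments` with complex coefficient
#'   array `coef` [channels x segments x bins], the bin frequencies
#'   `freqs`, `delta_f`, `segment_length` and channel labels.
#' @export
segment_fft <- function(recording, segment_seconds = 1, freqs = NULL) {
  data <- recording$data
  fs <- recording$fs
  sl <- round(segment_seconds * fs)
  n <- nrow(data)
  L <- floor(ncol(data) / sl)
  if (L < 2) stop("recording shorter than two segments")
  delta_f <- fs / sl
  w <- signal::hanning(sl)
  # segments as columns: [sl x (L*n)], channel-major blocks
  X <- matrix(t(data[, seq_len(L * sl), drop = FALSE]), nrow = sl)
  X <- X * w
  if (is.null(freqs)) {
    sp <- stats::mvfft(X)[seq_len(sl %/% 2 + 1), , drop = FALSE]
    freqs_out <- (seq_len(sl %/% 2 + 1) - 1) * delta_f
  } else {
    k <- freqs / delta_f
    if (any(abs(k - round(k)) > 1e-9) || any(k < 0) || any(k > sl / 2))
      stop("requested frequencies must sit on the segment bin grid below Nyquist")
    k <- round(k)
    tt <- seq_len(sl) - 1
    E <- exp(-2i * pi * outer(tt, k) / sl)
    sp <- t(t(X) %*% E)                # [nbins x (L*n)]
    freqs_out <- k * delta_f
  }
  co <- aperm(array(t(sp), dim = c(L, n, length(freqs_out))), c(2, 1, 3))
  dimnames(co) <- list(rownames(data), NULL, NULL)
  structure(list(coef = co, freqs = freqs_out, fs = fs, delta_f = delta_f,
                 segment_length = sl, window = "hanning",
                 labels = rownames(data)),
            class = "spectral_segments")
}

#' @export
print.spectral_segments <- function(x, ...) {
  cat(sprintf("Spectral segments: %d channels x %d segments x %d bins (df = %g Hz)\n",
              dim(x$coef)[1], dim(x$coef)[2], dim(x$coef)[3], x$delta_f))
  invisible(x)
}

# resolve a frequency (Hz) to a bin index of S
fbin <- function(S, f) {
  i <- which(abs(S$freqs - f) < 1e-9)
  if (length(i) != 1)
    stop(sprintf("frequency %g Hz not on the segment grid", f))
  i
}

# resolve a channel (index or label)
chan_index <- function(S, i) {
  if (is.character(i)) {
    j <- match(i, S$labels)
    if (is.na(j)) stop(sprintf("unknown channel '%s'", i))
    return(j)
  }
  as.integer(i)
}

#' Auto-bispectrum at one frequency pair
#'
#' Segment-mean triple product
#' `B_i(f1, f2) = (1/L) sum_l v_i(f1,l) v_i(f2,l) Conj(v_i(f1+f2,l))`.
#'
#' @param S a [segment_fft()] result.
#' @param i channel index or label.
#' @param f1,f2 frequencies in Hz; `f1 + f2` must be on the grid (below
#'   Nyquist).
#' @return A complex scalar.
#' @export
auto_bispectrum <- function(S, i, f1, f2) {
  i <- chan_index(S, i)
  b1 <- fbin(S, f1); b2 <- fbin(S, f2); b3 <- fbin(S, f1 + f2)
  mean(S$coef[i, , b1] * S$coef[i, , b2] * Conj(S$coef[i, , b3]))
}

#' Segment three-norm of Fourier coefficients
#'
#' `Q_i(f) = ((1/L) sum_l |v_i(f,l)|^3)^(1/3)`, the normalization used to
#' bound bicoherence magnitudes by one.
#'
#' @inheritParams auto_bispectrum
#' @param f frequency, Hz.
#' @return Non-negative scalar.
#' @export
three_norm <- function(S, i, f) {
  i <- chan_index(S, i)
  (mean(abs(S$coef[i, , fbin(S, f)])^3))^(1 / 3)
}

# ratio with 0/0 -> 0 + warning
safe_ratio <- function(num, den, what, warn = TRUE) {
  zero <- den == 0
  if (any(zero)) {
    if (warn)
      warning(sprintf("%s: zero normalization in %d entr%s; value set to 0",
                      what, sum(zero), if (sum(zero) == 1) "y" else "ies"))
    den[zero] <- 1
    num[zero] <- 0
  }
  num / den
}

#' Bicoherence
#'
#' Normalized auto-bispectrum `b_i = B_i / (Q_i(f1) Q_i(f2) Q_i(f1+f2))`;
#' the magnitude is bounded by 1 (Hoelder inequality with exponents 3,3,3
#' on the empirical segment measure).
#'
#' @inheritParams auto_bispectrum
#' @return A complex scalar with `Mod(.) <= 1`.
#' @export
bicoherence <- function(S, i, f1, f2) {
  B <- auto_bispectrum(S, i, f1, f2)
  N <- three_norm(S, i, f1) * three_norm(S, i, f2) * three_norm(S, i, f1 + f2)
  safe_ratio(B, N, "bicoherence")
}

#' Cross-bicoherence for one ordered channel triplet
#'
#' `cb_ijk = <v_i(f1) v_j(f2) Conj(v_k(f1+f2))> / (Q_i(f1) Q_j(f2) Q_k(f1+f2))`.
#'
#' @inheritParams auto_bispectrum
#' @param j,k second and third channel (index or label).
#' @return A complex scalar with `Mod(.) <= 1`.
#' @export
cross_bicoherence <- function(S, i, j, k, f1, f2) {
  i <- chan_index(S, i); j <- chan_index(S, j); k <- chan_index(S, k)
  b1 <- fbin(S, f1); b2 <- fbin(S, f2); b3 <- fbin(S, f1 + f2)
  B <- mean(S$coef[i, , b1] * S$coef[j, , b2] * Conj(S$coef[k, , b3]))
  N <- three_norm(S, i, f1) * three_norm(S, j, f2) * three_norm(S, k, f1 + f2)
  safe_ratio(B, N, "cross_bicoherence")
}

#' Antisymmetric cross-bicoherence for one ordered triplet
#'
#' `acb_ijk = (B_ijk - B_kji) / (N_ijk + N_kji)`: the normalized difference
#' of two cross-bispectra with the outer channel indices swapped.  It
#' vanishes identically for any instantaneous superposition of independent
#' sources, which suppresses volume-conduction artifacts.
#'
#' @inheritParams cross_bicoherence
#' @return A complex scalar with `Mod(.) <= 1`; exactly 0 when `i == k`.
#' @export
antisym_cross_bicoherence <- function(S, i, j, k, f1, f2) {
  i <- chan_index(S, i); j <- chan_index(S, j); k <- chan_index(S, k)
  b1 <- fbin(S, f1); b2 <- fbin(S, f2); b3 <- fbin(S, f1 + f2)
  Bijk <- mean(S$coef[i, , b1] * S$coef[j, , b2] * Conj(S$coef[k, , b3]))
  Bkji <- mean(S$coef[k, , b1] * S$coef[j, , b2] * Conj(S$coef[i, , b3]))
  Nijk <- three_norm(S, i, f1) * three_norm(S, j, f2) * three_norm(S, k, f1 + f2)
  Nkji <- three_norm(S, k, f1) * three_norm(S, j, f2) * three_norm(S, i, f1 + f2)
  safe_ratio(Bijk - Bkji, Nijk + Nkji, "antisym_cross_bicoherence")
}

#' Per-channel bicoherence vector at one frequency pair
#'
#' @inheritParams auto_bispectrum
#' @return Named complex vector over channels.
#' @export
bicoherence_channels <- function(S, f1, f2) {
  b1 <- fbin(S, f1); b2 <- fbin(S, f2); b3 <- fbin(S, f1 + f2)
  V1 <- S$coef[, , b1, drop = FALSE][, , 1]
  V2 <- S$coef[, , b2, drop = FALSE][, , 1]
  V3 <- S$coef[, , b3, drop = FALSE][, , 1]
  B <- rowMeans(V1 * V2 * Conj(V3))
  Q <- function(V) rowMeans(abs(V)^3)^(1 / 3)
  out <- safe_ratio(B, Q(V1) * Q(V2) * Q(V3), "bicoherence")
  names(out) <- S$labels
  out
}

# all-ordered-triplet cross-bispectrum tensor via per-segment rank-3
# accumulation (Khatri-Rao product); identical to the naive triple loop
cross_bispectrum_tensor <- function(V1, V2, V3) {
  n <- nrow(V1); L <- ncol(V1)
  KR <- V1[rep(seq_len(n), times = n), , drop = FALSE] *
        V2[rep(seq_len(n), each = n), , drop = FALSE]
  array(KR %*% t(Conj(V3)) / L, dim = c(n, n, n))
}

#' Cross- and antisymmetric cross-bicoherence over all ordered triplets
#'
#' Computes the full `[N x N x N]` tensor of `cb_ijk` (and `acb_ijk`) at
#' one frequency pair, organized as a per-segment outer-product
#' accumulation so that high-density montages remain tractable.
#'
#' @inheritParams auto_bispectrum
#' @param measure `"cb"` or `"acb"`.
#' @return Complex array `[N x N x N]` indexed `[i, j, k]`.
#' @export
triplet_tensor <- function(S, f1, f2, measure = c("cb", "acb")) {
  measure <- match.arg(measure)
  b1 <- fbin(S, f1); b2 <- fbin(S, f2); b3 <- fbin(S, f1 + f2)
  V1 <- S$coef[, , b1, drop = FALSE][, , 1, drop = TRUE]
  V2 <- S$coef[, , b2, drop = FALSE][, , 1, drop = TRUE]
  V3 <- S$coef[, , b3, drop = FALSE][, , 1, drop = TRUE]
  if (is.null(dim(V1))) { V1 <- rbind(V1); V2 <- rbind(V2); V3 <- rbind(V3) }
  B <- cross_bispectrum_tensor(V1, V2, V3)
  Q <- function(V) rowMeans(abs(V)^3)^(1 / 3)
  Nijk <- outer(outer(Q(V1), Q(V2)), Q(V3))
  if (measure == "cb") {
    safe_ratio(B, Nijk, "cross_bicoherence")
  } else {
    safe_ratio(B - aperm(B, c(3, 2, 1)), Nijk + aperm(Nijk, c(3, 2, 1)),
               "antisym_cross_bicoherence")
  }
}

#' Seed-based connectivity maps
#'
#' Bivariate versions of the triplet measures with the seed channel used
#' for both `i` and `j`: the value at channel `k` is `measure(seed, seed, k)`.
#' For `acb` the entry at the seed itself is exactly 0.
#'
#' @inheritParams auto_bispectrum
#' @param seed_channel seed label or index.
#' @param measure `"cb"` or `"acb"`.
#' @return Named complex vector over channels.
#' @export
seed_maps <- function(S, seed_channel, f1, f2, measure = c("cb", "acb")) {
  measure <- match.arg(measure)
  s <- chan_index(S, seed_channel)
  n <- dim(S$coef)[1]
  fun <- if (measure == "cb") cross_bicoherence else antisym_cross_bicoherence
  out <- vapply(seq_len(n), function(k) fun(S, s, s, k, f1, f2), complex(1))
  names(out) <- S$labels
  out
}

#' Bicoherence scan over a frequency plane
#'
#' Evaluates bicoherence of one channel for all pairs `(f1, f2)` on the
#' segment grid with `f1, f2 >= delta_f` and `f1 + f2 <= fmax_sum`, and
#' locates the peak magnitude (ties broken by lowest `f1`, then lowest
#' `f2`).  Both orderings of each pair are kept; the plane is symmetric
#' for auto-bicoherence.
#'
#' @inheritParams auto_bispectrum
#' @param fmax_sum largest `f1 + f2` scanned, Hz (must be at or below
#'   Nyquist).
#' @return List with `table` (data.frame `f1`, `f2`, `value`, `magnitude`)
#'   and `peak` (named vector `f1`, `f2`).
#' @export
bicoherence_scan <- function(S, i, fmax_sum = 40) {
  if (fmax_sum > S$fs / 2) stop("fmax_sum must not exceed the Nyquist frequency")
  i <- chan_index(S, i)
  df <- S$delta_f
  f1s <- seq(df, fmax_sum - df, by = df)
  rows <- do.call(rbind, lapply(f1s, function(f1) {
    f2s <- seq(df, fmax_sum - f1, by = df)
    data.frame(f1 = f1, f2 = f2s)
  }))
  # order guarantees the tie rule: lowest f1 first, then lowest f2
  rows <- rows[order(rows$f1, rows$f2), ]
  val <- mapply(function(a, b) bicoherence(S, i, a, b), rows$f1, rows$f2)
  rows$value <- val
  rows$magnitude <- abs(val)
  peak <- rows[which.max(rows$magnitude), ]
  list(table = rows, peak = c(f1 = peak$f1, f2 = peak$f2))
}

#' Maximum bicoherence over channels
#'
#' @param b named numeric (or complex) vector of per-channel bicoherence
#'   values; magnitudes are compared.  Ties resolve to the lowest channel
#'   index.
#' @return List with `value` (magnitude) and `channel` (label or index).
#' @export
b_max <- function(b) {
  if (length(b) == 0) stop("empty input")
  m <- abs(b)
  j <- which.max(m)            # which.max returns the first maximum
  lab <- if (!is.null(names(b))) names(b)[j] else j
  list(value = as.numeric(m[j]), channel = lab)
}
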