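#' Per-channel paired t-statistics
#'
#' Classic paired t-test on per-subject differences, vectorized over
#' channels.  Channels with zero-variance differences yield `NA` with a
#' warning.
#'
#' @param maps_a,maps_b numeric matrices [subjects x channels] of
#'   per-subject per-channel magnitudes under two conditions (matched
#'   subject order).
#' @return Numeric vector of t-values, one per channel.
#' @export
paired_t <- function(maps_a, maps_b) {
  maps_a <- as.matrix(maps_a); maps_b <- as.matrix(maps_b)
  if (!all(dim(maps_a) == dim(maps_b)))
    stop("the two condition matrices must have identical subjects x channels shape")
  n <- nrow(maps_a)
  if (n < 2) stop("need at least 2 subjects")
  t_from_diff(maps_a - maps_b, warn = TRUE)
}

# t of paired differences with the degenerate-variance convention:
# identically-zero differences give t = 0 (identical conditions); a
# constant non-zero shift has no within-subject variability and t is
# undefined (NA, flagged)
t_from_diff <- function(d, warn = FALSE) {
  n <- nrow(d)
  mu <- colMeans(d)
  sdv <- apply(d, 2, stats::sd)
  tt <- mu / (sdv / sqrt(n))
  zero <- sdv == 0
  if (any(zero)) {
    tt[zero & mu == 0] <- 0
    undef <- zero & mu != 0
    if (any(undef)) {
      if (warn)
        warning(sprintf("%d channel(s) with zero-variance differences: t undefined",
                        sum(undef)))
      tt[undef] <- NA_real_
    }
  }
  tt
}

#' Permutation p-values for paired condition maps
#'
#' The null distribution is built by randomly swapping the two conditions
#' within each subject (equivalently, sign-flipping each subject's paired
#' difference) and recomputing the t-statistic; the two-tailed p-value is
#' the proportion of permutations with `|t_perm| >= |t_obs|`.  With
#' `p_plus_one = TRUE` (default) the observed partition is counted once:
#' `p = (1 + #exceed) / (1 + n_perm)`, so p is never exactly 0.  When
#' `2^n_subjects <= n_perm` the sign patterns are enumerated exhaustively
#' instead and p is the exact proportion over all `2^n` patterns.
#'
#' @inheritParams paired_t
#' @param n_perm number of random partitions (default 10000).
#' @param seed integer seed for the random partitions.
#' @param p_plus_one use the add-one convention for random permutations.
#' @return List: `t` (observed t per channel), `p` (per channel),
#'   `n_perm_used`, `exhaustive`.
#' @export
permutation_p <- function(maps_a, maps_b, n_perm = 10000, seed = 1L,
                          p_plus_one = TRUE) {
  t_obs <- paired_t(maps_a, maps_b)
  d <- as.matrix(maps_a) - as.matrix(maps_b)
  n <- nrow(d)
  tstat <- function(dd) t_from_diff(dd)
  exhaustive <- 2^n <= n_perm
  if (!exhaustive && n_perm < 100)
    warning("fewer than 100 permutations: p-values are coarse")
  if (exhaustive) {
    signs <- as.matrix(expand.grid(rep(list(c(1, -1)), n)))
    tp <- apply(signs, 1, function(s) abs(tstat(d * s)))
    tp <- matrix(tp, ncol = nrow(signs))       # channels x patterns
    p <- rowMeans(tp >= abs(t_obs) - 1e-12)
    used <- nrow(signs)
  } else {
    set.seed(seed)
    exceed <- numeric(length(t_obs))
    for (b in seq_len(n_perm)) {
      s <- sample(c(1, -1), n, replace = TRUE)
      exceed <- exceed + (abs(tstat(d * s)) >= abs(t_obs) - 1e-12)
    }
    p <- if (p_plus_one) (1 + exceed) / (1 + n_perm) else exceed / n_perm
    used <- n_perm
  }
  p[is.na(t_obs)] <- NA_real_
  list(t = t_obs, p = p, n_perm_used = used, exhaustive = exhaustive)
}

#' Benjamini-Hochberg false discovery rate control
#'
#' Step-up FDR adjustment of raw p-values; the significance mask rejects
#' hypotheses with adjusted p below `q`.
#'
#' @param p_values raw p-values in (0, 1].
#' @param q FDR level (default 0.05).
#' @return List: `p_adjusted`, `mask` (logical), `q`.
#' @export
fdr_correct <- function(p_values, q = 0.05) {
  if (any(p_values <= 0 | p_values > 1, na.rm = TRUE))
    stop("p-values must lie in (0, 1]")
  adj <- stats::p.adjust(p_values, method = "BH")
  list(p_adjusted = adj, mask = !is.na(adj) & adj < q, q = q)
}

#' Group statistics map for two reference schemes
#'
#' Bundles the paired t-map, permutation p-values, and both uncorrected
#' and FDR-corrected significance masks at level `alpha`.
#'
#' @inheritParams permutation_p
#' @param alpha significance level for the masks.
#' @return Object of class `stat_map` with fields `t`, `p`, `p_fdr`,
#'   `mask_uncorrected`, `mask_fdr`, `n_subjects`, `n_perm`, `seed`.
#' @export
compare_maps <- function(maps_a, maps_b, n_perm = 10000, seed = 1L,
                         alpha = 0.05, p_plus_one = TRUE) {
  pp <- permutation_p(maps_a, maps_b, n_perm = n_perm, seed = seed,
                      p_plus_one = p_plus_one)
  fdr <- fdr_correct(pp$p, q = alpha)
  structure(list(t = pp$t, p = pp$p, p_fdr = fdr$p_adjusted,
                 mask_uncorrected = !is.na(pp$p) & pp$p < alpha,
                 mask_fdr = fdr$mask,
                 n_subjects = nrow(as.matrix(maps_a)),
                 n_perm = pp$n_perm_used, seed = seed),
            class = "stat_map")
}

#' @export
print.stat_map <- function(x, ...) {
  cat(sprintf(
    "Group stat map: %d channels, n = %d subjects, %d permutations\n",
    length(x$t), x$n_subjects, x$n_perm))
  cat(sprintf("  significant channels: %d uncorrected, %d FDR-corrected\n",
              sum(x$mask_uncorrected, na.rm = TRUE),
              sum(x$mask_fdr, na.rm = TRUE)))
  invisible(x)
}

#' Group comparison of maximum bicoherence across reference schemes
#'
#' For each subject recording and each scheme, applies the re-referencing
#' transform, estimates per-channel bicoherence at `(f1, f2)` and takes
#' its maximum over channels.  Reports the across-subject mean and
#' standard error per scheme, with pairwise permutation tests on the
#' per-subject values and FDR correction across pairs.
#'
#' @param recordings list of [eeg_recording()]s (one per subject), all
#'   under a common reference.
#' @param transforms named list of [ref_transform()]s (or plain matrices)
#'   mapping the recordings' reference to each scheme.
#' @param f1,f2 frequency pair, Hz.
#' @param n_perm,seed,q permutation and FDR settings.
#' @return List: `bmax` (matrix subjects x schemes), `table`
#'   (mean/se per scheme), `pairwise` (data.frame with t, p, p_fdr).
#' @export
bmax_comparison <- function(recordings, transforms, f1 = 6, f2 = 10,
                            n_perm = 10000, seed = 1L, q = 0.05) {
  if (length(recordings) < 2) stop("need at least 2 subjects")
  if (length(transforms) < 2) stop("need at least 2 schemes")
  if (is.null(names(transforms)) || any(names(transforms) == ""))
    stop("`transforms` must be a named list")
  mats <- lapply(transforms, function(tr) if (inherits(tr, "ref_transform")) tr$matrix else tr)
  bm <- sapply(names(mats), function(s) {
    vapply(recordings, function(rec) {
      rec_x <- rec
      rec_x$data <- mats[[s]] %*% rec$data
      S <- segment_fft(rec_x, freqs = c(f1, f2, f1 + f2))
      b_max(abs(bicoherence_channels(S, f1, f2)))$value
    }, numeric(1))
  })
  tab <- data.frame(scheme = colnames(bm),
                    mean = colMeans(bm),
                    se = apply(bm, 2, stats::sd) / sqrt(nrow(bm)))
  pairs <- utils::combn(colnames(bm), 2)
  pw <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(ii) {
    a <- pairs[1, ii]; b <- pairs[2, ii]
    pp <- permutation_p(bm[, a, drop = FALSE], bm[, b, drop = FALSE],
                        n_perm = n_perm, seed = seed + ii)
    data.frame(scheme_a = a, scheme_b = b, t = pp$t, p = pp$p)
  }))
  pw$p_fdr <- fdr_correct(pw$p, q = q)$p_adjusted
  rownames(pw) <- NULL
  rownames(tab) <- NULL
  list(bmax = bm, table = tab, pairwise = pw)
}
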