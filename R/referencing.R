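#' Re-referencing transform
#'
#' An N x N matrix `T` mapping channel data under the acquisition reference
#' to data under the target scheme, `V_X = T V`.  For Cz, DLM and AVE the
#' matrix is `I - R` where `R` holds copies of the reference signal: ones in
#' the Cz column, 0.5 in the two mastoid columns, or 1/N everywhere.  These
#' transforms annihilate common offsets (zero row sums) and are idempotent.
#'
#' @param matrix numeric [N x N] matrix.
#' @param scheme one of `"Cz"`, `"DLM"`, `"AVE"`, `"REST"`.
#' @param provenance descriptor list (head model / ESD for REST).
#' @return An object of class `ref_transform`.
#' @export
ref_transform <- function(matrix, scheme, provenance = list()) {
  scheme <- match.arg(scheme, c("Cz", "DLM", "AVE", "REST"))
  matrix <- as.matrix(matrix)
  if (nrow(matrix) != ncol(matrix)) stop("transform must be square")
  structure(list(matrix = matrix, scheme = scheme, provenance = provenance),
            class = "ref_transform")
}

#' @export
print.ref_transform <- function(x, ...) {
  cat(sprintf("Reference transform: scheme %s, %d x %d\n", x$scheme,
              nrow(x$matrix), ncol(x$matrix)))
  invisible(x)
}

#' Cz, linked-mastoids and average reference transforms
#'
#' @param scheme `"Cz"`, `"DLM"` or `"AVE"`.
#' @param layout an [electrode_layout()] supplying the vertex and mastoid
#'   labels.
#' @return A [ref_transform()].
#' @examples
#' lay <- make_layout(21)
#' T_ave <- make_simple_transform("AVE", lay)
#' max(abs(rowSums(T_ave$matrix)))  # annihilates common offsets
#' @export
make_simple_transform <- function(scheme, layout) {
  scheme <- match.arg(scheme, c("Cz", "DLM", "AVE"))
  n <- length(layout$names)
  R <- matrix(0, n, n)
  if (scheme == "Cz") {
    j <- match(layout$vertex, layout$names)
    if (is.na(j)) stop("vertex label missing from layout")
    R[, j] <- 1
  } else if (scheme == "DLM") {
    j <- match(layout$mastoid_pair, layout$names)
    if (anyNA(j)) stop("mastoid labels missing from layout")
    R[, j] <- 0.5
  } else {
    R[] <- 1 / n
  }
  M <- diag(n) - R
  dimnames(M) <- list(layout$names, layout$names)
  ref_transform(M, scheme, provenance = list(layout_density = layout$density_tag))
}

# quasi-uniform points on a disk via a sunflower (golden-angle) spiral
sunflower_disk <- function(n, radius) {
  k <- seq_len(n)
  ga <- pi * (3 - sqrt(5))
  r <- radius * sqrt((k - 0.5) / n)
  th <- k * ga
  cbind(r * cos(th), r * sin(th))
}

#' Equivalent source distribution surface
#'
#' A closed dipole layer for the REST construction: a spherical cap (polar
#' angle 0 to `cap_angle_deg`) at `cap_scale` times the brain radius,
#' closed on the bottom by a transverse disk.  Dipoles are quasi-uniform
#' (Fibonacci spiral on the cap, golden-angle sunflower on the disk) and
#' normally oriented: radially outward on the cap, downward on the disk.
#' Deterministic given `count`.
#'
#' @param model a [head_model()].
#' @param count total number of dipoles (default 4000).
#' @param cap_angle_deg polar extent of the cap in degrees.
#' @param cap_scale cap radius as a fraction of the brain radius.
#' @return A `dipole_set` with `role = "esd"`.
#' @export
build_esd <- function(model, count = 4000, cap_angle_deg = 130, cap_scale = 0.95) {
  stopifnot(inherits(model, "head_model"))
  if (count < 100) stop("count must be >= 100")
  if (cap_angle_deg <= 0 || cap_angle_deg >= 180)
    stop("cap_angle_deg must lie in (0, 180)")
  if (cap_scale <= 0 || cap_scale >= 1) stop("cap_scale must lie in (0, 1)")
  r <- cap_scale * model$radii[1]
  th_max <- cap_angle_deg * pi / 180
  a_cap <- 2 * pi * r^2 * (1 - cos(th_max))
  rho <- r * sin(th_max)
  a_disk <- pi * rho^2
  n_cap <- max(1L, round(count * a_cap / (a_cap + a_disk)))
  n_disk <- count - n_cap

  # Fibonacci spiral on the cap: uniform in cos(theta) over [cos(th_max), 1]
  k <- seq_len(n_cap)
  z <- 1 - (k - 0.5) / n_cap * (1 - cos(th_max))
  th <- acos(z)
  ga <- pi * (3 - sqrt(5))
  az <- k * ga
  cap_pos <- cbind(r * sin(th) * cos(az), r * sin(th) * sin(az), r * z)
  cap_nrm <- cap_pos / r

  disk_xy <- sunflower_disk(n_disk, rho)
  disk_pos <- cbind(disk_xy, rep(r * cos(th_max), n_disk))
  disk_nrm <- cbind(0 * disk_xy[, 1], 0 * disk_xy[, 1], rep(-1, n_disk))

  pos <- sweep(rbind(cap_pos, disk_pos), 2, model$center, "+")
  nrm <- rbind(cap_nrm, disk_nrm)
  dipole_set(pos, nrm, role = "esd", model = model)
}

# Moore-Penrose pseudoinverse with relative singular-value truncation
pinv_trunc <- function(A, rtol = 1e-8) {
  sv <- svd(A)
  keep <- sv$d > rtol * sv$d[1]
  rank <- sum(keep)
  if (rank < min(dim(A)))
    message(sprintf("pseudoinverse: effective rank %d of %d", rank, min(dim(A))))
  Ainv <- sv$v[, keep, drop = FALSE] %*%
    (t(sv$u[, keep, drop = FALSE]) / sv$d[keep])
  list(pinv = Ainv, rank = rank)
}

#' REST (reference electrode standardization) transform
#'
#' Builds `T_REST = G_inf pinv(G_m)` where `G_inf` is the
#' infinity-referenced lead field of the equivalent source distribution and
#' `G_m` the same lead field under the acquisition reference (Cz by
#' default, matching an acquisition referenced at the vertex).  The
#' pseudoinverse truncates singular values below `rtol` times the largest.
#' Applying the transform to data under the acquisition reference yields an
#' approximation of the infinity-referenced data.
#'
#' @param layout an [electrode_layout()].
#' @param model_for_rest the [head_model()] assumed when building the
#'   transform (may differ from the model that generated the data).
#' @param esd an ESD [dipole_set()] from [build_esd()]; built with defaults
#'   when omitted.
#' @param acquisition_reference scheme the input data are referenced to
#'   (`"Cz"` default).
#' @param rtol relative pseudoinverse truncation tolerance.
#' @return A [ref_transform()] with `scheme = "REST"`.
#' @export
make_rest_transform <- function(layout, model_for_rest, esd = NULL,
                                acquisition_reference = "Cz", rtol = 1e-8) {
  stopifnot(inherits(layout, "electrode_layout"),
            inherits(model_for_rest, "head_model"))
  if (is.null(esd)) esd <- build_esd(model_for_rest)
  # project the electrodes onto the scalp sphere of the assumed model: a
  # mismatched REST model carries its own scalp radius
  dirs <- sweep(layout$positions, 2, model_for_rest$center)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  lay_rest <- electrode_layout(
    layout$names,
    sweep(dirs * model_for_rest$radii[3], 2, model_for_rest$center, "+"),
    mastoid_pair = layout$mastoid_pair, vertex = layout$vertex,
    density_tag = layout$density_tag, center = model_for_rest$center)
  G_inf <- leadfield(esd, lay_rest, model_for_rest)
  T_acq <- make_simple_transform(acquisition_reference, layout)
  G_m <- T_acq$matrix %*% G_inf
  pi_ <- pinv_trunc(G_m, rtol = rtol)
  M <- G_inf %*% pi_$pinv
  dimnames(M) <- list(layout$names, layout$names)
  ref_transform(M, "REST",
                provenance = list(model = model_for_rest,
                                  n_esd = nrow(esd$positions),
                                  acquisition_reference = acquisition_reference,
                                  rtol = rtol, effective_rank = pi_$rank))
}

#' Apply a reference transform to a recording
#'
#' @param transform a [ref_transform()].
#' @param recording an [eeg_recording()].
#' @return A re-referenced [eeg_recording()] with updated reference tag.
#' @export
apply_transform <- function(transform, recording) {
  stopifnot(inherits(transform, "ref_transform"),
            inherits(recording, "eeg_recording"))
  if (ncol(transform$matrix) != nrow(recording$data))
    stop("transform and recording dimensions disagree")
  out <- recording
  out$data <- transform$matrix %*% recording$data
  rownames(out$data) <- recording$layout$names
  out$reference <- transform$scheme
  out$provenance <- c(recording$provenance,
                      list(rereference = transform$provenance))
  out
}
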