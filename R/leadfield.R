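#' @name leadfield
#' @rdname leadfield
NULL

# Per-degree gain factors for the three-shell concentric-sphere solution.
#
# For each spherical-harmonic degree n the potential in each compartment is
# a combination of r^n and r^-(n+1) terms; matching potential and radial
# current density at the two inner interfaces and imposing zero radial
# current at the scalp surface yields a 5x5 linear system per degree.  The
# basis functions are localized to the interfaces ((r/r_j)^n, (r_j/r)^(n+1))
# so that every matrix entry is O(1) and the solve is stable up to n = 200.
#
# Radii are expressed in units of the scalp radius.  The returned gain g_n
# is the ratio between the surface-potential coefficient and the source
# coefficient of the r^-(n+1) term in the brain compartment, such that
#
#   V(e) = 1/(4 pi sigma_1 R3^2) * sum_n g_n b^(n-1)
#          * [ n q_r P_n(x) + P_n'(x) (q.rhat - x q_r) ]
#
# with b the dipole eccentricity in scalp-radius units, x = cos(angle
# between dipole position and electrode), q_r the radial moment component.
shell_gains <- function(model, nmax = 200L) {
  r <- model$radii / model$radii[3]
  s <- model$conductivities
  r1 <- r[1]; r2 <- r[2]
  g <- numeric(nmax)
  for (n in seq_len(nmax)) {
    p12 <- (r1 / r2)^n          # (r1/r2)^n
    q12 <- (r1 / r2)^(n + 1)    # (r1/r2)^(n+1)
    r2n <- r2^n
    r2n1 <- r2^(n + 1)
    # unknowns: a1, a2, b2, a3, b3 (interface-localized bases)
    # region 1: a1 (r/r1)^n + source (value 1 at r1 by scaling)
    # region 2: a2 (r/r2)^n + b2 (r1/r)^(n+1)
    # region 3: a3 r^n      + b3 (r2/r)^(n+1)
    A <- matrix(0, 5, 5)
    bvec <- numeric(5)
    # potential continuity at r1
    A[1, ] <- c(1, -p12, -1, 0, 0)
    bvec[1] <- -1
    # current continuity at r1: sigma * dV/dr, common factor 1/r1 dropped
    A[2, ] <- c(s[1] * n, -s[2] * n * p12, s[2] * (n + 1), 0, 0)
    bvec[2] <- s[1] * (n + 1)
    # potential continuity at r2
    A[3, ] <- c(0, 1, q12, -r2n, -1)
    # current continuity at r2 (common factor 1/r2 dropped)
    A[4, ] <- c(0, s[2] * n, -s[2] * (n + 1) * q12, -s[3] * n * r2n, s[3] * (n + 1))
    # insulating scalp boundary at r = 1
    A[5, ] <- c(0, 0, 0, n, -(n + 1) * r2n1)
    x <- solve(A, bvec)
    # surface potential / source coefficient; source scaling was r1^(n+1)
    g[n] <- (x[4] + x[5] * r2n1) / r1^(n + 1)
  }
  g
}

#' Infinity-referenced lead field for a spherical three-shell head
#'
#' Computes the scalp potentials generated by unit current dipoles inside the
#' brain compartment of a three-concentric-shell spherical volume conductor,
#' referenced to a point at infinity (no reference electrode subtracted).
#' The solution is the truncated Legendre series for concentric shells; the
#' series is truncated when the relative magnitude of the current term drops
#' below `tol` or after `nmax` terms.
#'
#' @param dipoles a [dipole_set()] with unit orientations; all positions must
#'   lie strictly inside the brain radius.
#' @param layout an [electrode_layout()] (positions on the scalp sphere).
#' @param model a [head_model()].
#' @param nmax maximum series degree (default 200).
#' @param tol relative truncation tolerance (default 1e-12).
#' @return Numeric matrix [n_electrodes x n_dipoles], volts per (A m).
#' @export
leadfield <- function(dipoles, layout, model, nmax = 200L, tol = 1e-12) {
  stopifnot(inherits(dipoles, "dipole_set"), inherits(model, "head_model"))
  if (is.null(dipoles$orientations))
    stop("dipole orientations must be set before computing a lead field")
  R3 <- model$radii[3]
  pos <- sweep(dipoles$positions, 2, model$center)    # dipole positions, head frame
  epos <- sweep(layout$positions, 2, model$center)    # electrode positions
  er <- sqrt(rowSums(epos^2))
  if (any(abs(er - R3) > 1e-6 * R3))
    stop("electrode positions must lie on the scalp radius")
  b <- sqrt(rowSums(pos^2)) / R3                      # eccentricities (scalp units)
  if (any(b * R3 >= model$radii[1]))
    stop("all dipoles must lie strictly inside the brain shell")
  if (any(b < 1e-12))
    stop("dipole at the exact sphere center: radial direction undefined")
  q <- dipoles$orientations
  nd <- nrow(pos); ne <- nrow(epos)

  bhat <- pos / (b * R3)                              # unit position vectors
  ehat <- epos / er
  # elementwise outer-product sums rather than BLAS products: each column
  # is then computed identically regardless of how many dipoles share the
  # call, which keeps column-concatenation exact under superposition
  X <- outer(ehat[, 1], bhat[, 1]) + outer(ehat[, 2], bhat[, 2]) +
    outer(ehat[, 3], bhat[, 3])                       # cos(gamma), ne x nd
  X <- pmin(pmax(X, -1), 1)
  qr <- rowSums(q * bhat)                             # radial moment, length nd
  QdotE <- outer(ehat[, 1], q[, 1]) + outer(ehat[, 2], q[, 2]) +
    outer(ehat[, 3], q[, 3])                          # q . rhat, ne x nd

  gains <- shell_gains(model, nmax)
  # Legendre recurrences on the full ne x nd matrix
  Pm1 <- matrix(1, ne, nd)    # P_0
  P <- X                      # P_1
  Dm1 <- matrix(0, ne, nd)    # P_0'
  D <- matrix(1, ne, nd)      # P_1'
  QR <- matrix(qr, ne, nd, byrow = TRUE)
  Tang <- QdotE - X * QR
  V <- matrix(0, ne, nd)
  bpow <- rep(1, nd)          # b^(n-1)
  # truncation is decided per dipole (column), so that the series of one
  # dipole never depends on which other dipoles share the call
  active <- rep(TRUE, nd)
  for (n in seq_len(nmax)) {
    term <- gains[n] * sweep(n * QR * P + Tang * D, 2, bpow, "*")
    V[, active] <- V[, active] + term[, active]
    tmax <- apply(abs(term), 2, max)
    vmax <- pmax(apply(abs(V), 2, max), 1e-300)
    active <- active & !(tmax < tol * vmax)
    if (!any(active)) break
    if (n < nmax) {
      Pp1 <- ((2 * n + 1) * X * P - n * Pm1) / (n + 1)
      Dp1 <- (2 * n + 1) * P + Dm1
      Pm1 <- P; P <- Pp1
      Dm1 <- D; D <- Dp1
      bpow <- bpow * b
    }
  }
  V / (4 * pi * model$conductivities[1] * R3^2)
}
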