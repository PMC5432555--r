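#' Three-concentric-shell spherical head model
#'
#' Volume conductor consisting of three concentric spherical shells (brain,
#' skull, scalp) with piecewise-constant conductivity.  The default radii are
#' scaled from an adult head and the default conductivities are the standard
#' values for brain/scalp tissue and skull.
#'
#' @param radii numeric(3), strictly increasing boundary radii in meters:
#'   brain, skull, scalp.
#' @param conductivities numeric(3), conductivities in S/m for the brain,
#'   skull and scalp compartments.
#' @param center numeric(3), center of the spheres in meters.
#' @return An object of class `head_model`.
#' @examples
#' m <- head_model()
#' m$radii
#' @export
head_model <- function(radii = c(0.080, 0.085, 0.092),
                       conductivities = c(0.33, 0.0066, 0.33),
                       center = c(0, 0, 0)) {
  radii <- as.numeric(radii)
  conductivities <- as.numeric(conductivities)
  center <- as.numeric(center)
  if (length(radii) != 3L || any(diff(radii) <= 0))
    stop("`radii` must be three strictly increasing lengths (m)")
  if (length(conductivities) != 3L || any(conductivities <= 0))
    stop("`conductivities` must be three positive values (S/m)")
  if (length(center) != 3L || any(!is.finite(center)))
    stop("`center` must be a finite 3-D point")
  structure(
    list(radii = radii, conductivities = conductivities, center = center),
    class = "head_model"
  )
}

#' @export
print.head_model <- function(x, ...) {
  cat("Three-shell spherical head model\n")
  cat(sprintf("  radii (m):          %s\n", paste(format(x$radii), collapse = " / ")))
  cat(sprintf("  conductivity (S/m): %s\n", paste(format(x$conductivities), collapse = " / ")))
  cat(sprintf("  center (m):         [%s]\n", paste(format(x$center), collapse = ", ")))
  invisible(x)
}

#' Perturb a head model
#'
#' Returns a copy of the model with the brain and skull boundary radii
#' scaled by `radii_factor` (the scalp radius is kept, since the electrode
#' shell is observed) and the skull conductivity scaled by `skull_factor`.
#' Used to build the mismatched-model variant of REST, where the model
#' assumed for re-referencing differs from the one that generated the
#' data.  Scaling all three radii together would be a no-op: the REST
#' reconstruction map is invariant under a uniform rescaling of the
#' geometry, so a genuine mismatch must change the relative shell
#' geometry or the conductivity profile.
#'
#' @param model a [head_model()].
#' @param radii_factor multiplicative factor applied to the brain and
#'   skull boundary radii.
#' @param skull_factor multiplicative factor applied to the skull
#'   conductivity.
#' @return A perturbed `head_model`.
#' @export
perturb_model <- function(model, radii_factor = 0.90, skull_factor = 1.10) {
  stopifnot(inherits(model, "head_model"))
  if (radii_factor <= 0 || skull_factor <= 0)
    stop("perturbation factors must be positive")
  radii <- model$radii
  radii[1:2] <- radii[1:2] * radii_factor
  cond <- model$conductivities
  cond[2] <- cond[2] * skull_factor
  head_model(radii = radii, conductivities = cond, center = model$center)
}

#' Set of current dipoles
#'
#' @param positions numeric matrix [n x 3], positions in meters.
#' @param orientations numeric matrix [n x 3] of unit vectors, or `NULL` if
#'   orientations are assigned later (e.g. at sampling time).
#' @param role one of `"coupled"`, `"noise"`, `"esd"`.
#' @param model optional [head_model()]; if given, positions are checked to
#'   lie strictly inside the brain shell.
#' @return An object of class `dipole_set`.
#' @export
dipole_set <- function(positions, orientations = NULL, role = c("coupled", "noise", "esd"),
                       model = NULL) {
  role <- match.arg(role)
  positions <- as_matrix3(positions, "positions")
  n <- nrow(positions)
  if (!is.null(orientations)) {
    orientations <- as_matrix3(orientations, "orientations")
    if (nrow(orientations) != n)
      stop("`orientations` must have one row per dipole")
    nrm <- sqrt(rowSums(orientations^2))
    if (any(abs(nrm - 1) > 1e-9))
      stop("orientations must be unit vectors (|norm - 1| <= 1e-9)")
  }
  if (!is.null(model)) {
    r <- sqrt(rowSums(sweep(positions, 2, model$center)^2))
    if (any(r >= model$radii[1]))
      stop("all dipole positions must lie strictly inside the brain radius")
  }
  structure(list(positions = positions, orientations = orientations, role = role),
            class = "dipole_set")
}

#' @export
print.dipole_set <- function(x, ...) {
  cat(sprintf("Dipole set: %d dipoles, role = %s, orientations %s\n",
              nrow(x$positions), x$role,
              if (is.null(x$orientations)) "unset" else "set"))
  invisible(x)
}

# coerce to an n x 3 numeric matrix
as_matrix3 <- function(x, what) {
  if (is.null(dim(x))) x <- matrix(as.numeric(x), nrow = 1)
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (ncol(x) != 3L) stop(sprintf("`%s` must have 3 columns", what))
  if (any(!is.finite(x))) stop(sprintf("`%s` must be finite", what))
  x
}

#' Regular source grid inside the brain shell
#'
#' Candidate dipole positions on a regular Cartesian grid with the given
#' spacing, keeping only points strictly inside the brain radius.
#' Orientations are left unset; they are assigned when sources are sampled.
#'
#' @param model a [head_model()].
#' @param spacing grid step in meters (default 0.005, i.e. 5 mm).
#' @return A `dipole_set` with `role = "noise"`-agnostic positions and
#'   `orientations = NULL`.
#' @export
source_grid <- function(model, spacing = 0.005) {
  stopifnot(inherits(model, "head_model"))
  if (!is.numeric(spacing) || spacing <= 0) stop("`spacing` must be > 0")
  rb <- model$radii[1]
  if (spacing > 2 * rb) stop("`spacing` exceeds the brain diameter: empty grid")
  ax <- seq(-rb, rb, by = spacing)
  # symmetric grid about the center
  ax <- ax - mean(range(ax))
  g <- as.matrix(expand.grid(x = ax, y = ax, z = ax))
  inside <- rowSums(g^2) < rb^2
  if (!any(inside)) stop("`spacing` too large: empty grid")
  pos <- sweep(g[inside, , drop = FALSE], 2, model$center, "+")
  dimnames(pos) <- NULL
  structure(list(positions = pos, orientations = NULL, role = "noise"),
            class = "dipole_set")
}
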