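#' Electrode layout on the scalp sphere
#'
#' @param names character vector of unique channel labels.
#' @param positions numeric matrix [n x 3] of positions in meters; all must
#'   lie on a common sphere about `center` within 1e-6 relative tolerance.
#' @param mastoid_pair labels of the left/right mastoid(-proxy) channels.
#' @param vertex label of the vertex channel.
#' @param density_tag one of 21, 34, 74, 128 (or `NA` for ad-hoc layouts).
#' @param center sphere center in meters.
#' @return An object of class `electrode_layout`.
#' @export
electrode_layout <- function(names, positions, mastoid_pair = c("TP9", "TP10"),
                             vertex = "Cz", density_tag = NA_integer_,
                             center = c(0, 0, 0)) {
  positions <- as_matrix3(positions, "positions")
  names <- as.character(names)
  if (length(names) != nrow(positions)) stop("one label per position required")
  if (anyDuplicated(names)) stop("channel labels must be unique")
  r <- sqrt(rowSums(sweep(positions, 2, center)^2))
  radius <- mean(r)
  if (any(abs(r - radius) > 1e-6 * radius))
    stop("all positions must lie on a common scalp sphere (1e-6 relative)")
  for (lbl in c(mastoid_pair, vertex))
    if (!lbl %in% names)
      stop(sprintf("label '%s' not present in the layout", lbl))
  rownames(positions) <- names
  structure(list(names = names, positions = positions,
                 mastoid_pair = mastoid_pair, vertex = vertex,
                 density_tag = as.integer(density_tag),
                 radius = radius, center = as.numeric(center)),
            class = "electrode_layout")
}

#' @export
print.electrode_layout <- function(x, ...) {
  cat(sprintf("Electrode layout: %d channels (density tag %s), scalp radius %.3f m\n",
              length(x$names), x$density_tag, x$radius))
  cat(sprintf("  vertex %s; mastoids %s/%s\n", x$vertex,
              x$mastoid_pair[1], x$mastoid_pair[2]))
  invisible(x)
}

# spherical interpolation between two unit vectors
slerp <- function(a, b, f) {
  om <- acos(max(-1, min(1, sum(a * b))))
  if (om < 1e-12) return(a)
  (sin((1 - f) * om) * a + sin(f * om) * b) / sin(om)
}

unit_dir <- function(incl_deg, az_deg) {
  th <- incl_deg * pi / 180
  al <- az_deg * pi / 180
  c(sin(th) * sin(al), sin(th) * cos(al), cos(th))
}

# Idealized spherical electrode table in the spirit of the 10-20 / 10-10 /
# 10-5 placement systems.  Rows are arcs from a midline electrode to left
# and right outer-ring electrodes; the outer ring sits at 72 deg inclination
# (10% above the equatorial Nz-T9-Iz-T10 circle) and a few below-ring
# channels (T9/T10, TP9/TP10) sit on the equator.  Azimuth is measured from
# the nasion direction, positive to the right; odd numbers are left.
# The label set is an idealized stand-in: the placement systems fix the
# geometry, but published nets differ in which subset of labels they carry.
electrode_table_128 <- function() {
  rows <- list(
    # name, midline inclination, midline azimuth (0 front / 180 back),
    # ring azimuth magnitude, left labels (out->in? given in->out), right labels
    list(mid = "Fpz",  incl = 72, maz = 0,   raz = 18,
         lab = c("Fp1", "Fp2"), frac = c(1)),
    list(mid = "AFz",  incl = 54, maz = 0,   raz = 36,
         lab = c("AF1", "AF2", "AF3", "AF4", "AF5", "AF6", "AF7", "AF8"),
         frac = c(0.25, 0.5, 0.75, 1)),
    list(mid = "Fz",   incl = 36, maz = 0,   raz = 54,
         lab = c("F1", "F2", "F3", "F4", "F5", "F6", "F7", "F8"),
         frac = c(0.25, 0.5, 0.75, 1)),
    list(mid = "FCz",  incl = 18, maz = 0,   raz = 72,
         lab = c("FC1", "FC2", "FC3", "FC4", "FC5", "FC6", "FT7", "FT8"),
         frac = c(0.25, 0.5, 0.75, 1)),
    list(mid = "Cz",   incl = 0,  maz = 0,   raz = 90,
         lab = c("C1", "C2", "C3", "C4", "C5", "C6", "T7", "T8"),
         frac = c(0.25, 0.5, 0.75, 1)),
    list(mid = "CPz",  incl = 18, maz = 180, raz = 108,
         lab = c("CP1", "CP2", "CP3", "CP4", "CP5", "CP6", "TP7", "TP8"),
         frac = c(0.25, 0.5, 0.75, 1)),
    list(mid = "Pz",   incl = 36, maz = 180, raz = 126,
         lab = c("P1", "P2", "P3", "P4", "P5", "P6", "P7", "P8"),
         frac = c(0.25, 0.5, 0.75, 1)),
    list(mid = "POz",  incl = 54, maz = 180, raz = 144,
         lab = c("PO1", "PO2", "PO3", "PO4", "PO5", "PO6", "PO7", "PO8"),
         frac = c(0.25, 0.5, 0.75, 1)),
    list(mid = "Oz",   incl = 72, maz = 180, raz = 162,
         lab = c("O1", "O2"), frac = c(1)),
    # 10-5-style intermediate rows (h-labels), fractions offset from above
    list(mid = "AFFz", incl = 45, maz = 0,   raz = 45,
         lab = c("AFF1h", "AFF2h", "AFF3h", "AFF4h", "AFF5h", "AFF6h", "AFF7h", "AFF8h"),
         frac = c(0.125, 0.375, 0.625, 0.875)),
    list(mid = "FFCz", incl = 27, maz = 0,   raz = 63,
         lab = c("FFC1h", "FFC2h", "FFC3h", "FFC4h", "FFC5h", "FFC6h", "FFC7h", "FFC8h"),
         frac = c(0.125, 0.375, 0.625, 0.875)),
    list(mid = "FCCz", incl = 9,  maz = 0,   raz = 81,
         lab = c("FCC1h", "FCC2h", "FCC3h", "FCC4h", "FCC5h", "FCC6h", "FCC7h", "FCC8h"),
         frac = c(0.125, 0.375, 0.625, 0.875)),
    list(mid = "CCPz", incl = 9,  maz = 180, raz = 99,
         lab = c("CCP1h", "CCP2h", "CCP3h", "CCP4h", "CCP5h", "CCP6h", "CCP7h", "CCP8h"),
         frac = c(0.125, 0.375, 0.625, 0.875)),
    list(mid = "CPPz", incl = 27, maz = 180, raz = 117,
         lab = c("CPP1h", "CPP2h", "CPP3h", "CPP4h", "CPP5h", "CPP6h", "CPP7h", "CPP8h"),
         frac = c(0.125, 0.375, 0.625, 0.875)),
    list(mid = "PPOz", incl = 45, maz = 180, raz = 135,
         lab = c("PPO1h", "PPO2h", "PPO3h", "PPO4h", "PPO5h", "PPO6h", "PPO7h", "PPO8h"),
         frac = c(0.125, 0.375, 0.625, 0.875))
  )
  labs <- character(0)
  dirs <- NULL
  for (rw in rows) {
    m <- unit_dir(rw$incl, rw$maz)
    labs <- c(labs, rw$mid)
    dirs <- rbind(dirs, m)
    ringL <- unit_dir(72, -rw$raz)
    ringR <- unit_dir(72, rw$raz)
    nf <- length(rw$frac)
    for (k in seq_len(nf)) {
      f <- rw$frac[k]
      # labels come in (left, right) pairs ordered by increasing fraction
      lab_l <- rw$lab[2 * k - 1]
      lab_r <- rw$lab[2 * k]
      if (length(rw$frac) == 1) { lab_l <- rw$lab[1]; lab_r <- rw$lab[2] }
      labs <- c(labs, lab_l, lab_r)
      dirs <- rbind(dirs, slerp(m, ringL, f), slerp(m, ringR, f))
    }
  }
  # equatorial (below-ring) channels and poles of the sagittal circle
  low <- list(Nz = c(90, 0), Iz = c(90, 180),
              T9 = c(90, -90), T10 = c(90, 90),
              TP9 = c(90, -108), TP10 = c(90, 108))
  for (lbl in names(low)) {
    labs <- c(labs, lbl)
    dirs <- rbind(dirs, unit_dir(low[[lbl]][1], low[[lbl]][2]))
  }
  rownames(dirs) <- labs
  dirs
}

layout_labels <- function(density_tag) {
  l21 <- c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8", "T7", "C3", "Cz",
           "C4", "T8", "P7", "P3", "Pz", "P4", "P8", "O1", "O2", "TP9", "TP10")
  l34 <- c(l21, "AFz", "FC5", "FC1", "FC2", "FC6", "CP5", "CP1", "CP2",
           "CP6", "PO7", "POz", "PO8", "Oz")
  tab <- electrode_table_128()
  all_labs <- rownames(tab)
  l74 <- all_labs[!grepl("h$", all_labs) & !all_labs %in% c("AFFz", "FFCz",
          "FCCz", "CCPz", "CPPz", "PPOz", "Nz")]
  l128 <- all_labs[all_labs != "Nz"]
  switch(as.character(density_tag),
         "21" = l21, "34" = l34, "74" = l74, "128" = l128,
         stop(sprintf("unknown density tag '%s'; must be 21, 34, 74 or 128",
                      density_tag)))
}

#' Template electrode layout at a given density
#'
#' Returns the idealized spherical template layout for a 21-, 34-, 74- or
#' 128-channel montage, projected onto the scalp sphere of `model`.  The
#' label sets are nested: 21 in 34 in 74 in 128.  TP9/TP10 (on the
#' equatorial circle, near the mastoids) are included at every density and
#' serve as the mastoid pair for the linked-mastoids reference.
#'
#' @param density_tag 21, 34, 74 or 128.
#' @param model a [head_model()] fixing the scalp radius and center.
#' @return An [electrode_layout()].
#' @examples
#' lay <- make_layout(21)
#' lay$names
#' @export
make_layout <- function(density_tag, model = head_model()) {
  labs <- layout_labels(density_tag)
  tab <- electrode_table_128()
  dirs <- tab[labs, , drop = FALSE]
  # project onto the scalp sphere
  dirs <- dirs / sqrt(rowSums(dirs^2))
  pos <- sweep(dirs * model$radii[3], 2, model$center, "+")
  electrode_layout(labs, pos, mastoid_pair = c("TP9", "TP10"), vertex = "Cz",
                   density_tag = density_tag, center = model$center)
}

#' Read / write electrode layouts as .sfp-style text
#'
#' Whitespace-delimited text, one electrode per line: `label x y z` with
#' coordinates in meters.
#'
#' @param layout an [electrode_layout()].
#' @param path file path.
#' @param ... passed to [electrode_layout()] (e.g. `density_tag`).
#' @return `read_sfp` returns an [electrode_layout()]; `write_sfp` returns
#'   `path` invisibly.
#' @export
write_sfp <- function(layout, path) {
  df <- data.frame(label = layout$names,
                   x = layout$positions[, 1],
                   y = layout$positions[, 2],
                   z = layout$positions[, 3])
  utils::write.table(format(df, digits = 9, scientific = FALSE), path,
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_sfp
#' @export
read_sfp <- function(path, ...) {
  df <- utils::read.table(path, header = FALSE,
                          col.names = c("label", "x", "y", "z"),
                          stringsAsFactors = FALSE)
  electrode_layout(df$label, as.matrix(df[, c("x", "y", "z")]), ...)
}
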