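#' Canonical 64-channel Biosemi channel order
#'
#' Channel labels of the 64-electrode cap in the canonical order used
#' throughout the package (10-20 system extension, left hemisphere and
#' midline first, then right hemisphere).
#'
#' @return Character vector of 64 channel labels.
#' @export
biosemi64_labels <- function() {
  c("Fp1", "AF7", "AF3", "F1", "F3", "F5", "F7", "FT7", "FC5", "FC3",
    "FC1", "C1", "C3", "C5", "T7", "TP7", "CP5", "CP3", "CP1", "P1",
    "P3", "P5", "P7", "P9", "PO7", "PO3", "O1", "Iz", "Oz", "POz",
    "Pz", "CPz", "Fpz", "Fp2", "AF8", "AF4", "AFz", "Fz", "F2", "F4",
    "F6", "F8", "FT8", "FC6", "FC4", "FC2", "FCz", "Cz", "C2", "C4",
    "C6", "T8", "TP8", "CP6", "CP4", "CP2", "P2", "P4", "P6", "P8",
    "P10", "PO8", "PO4", "O2")
}

# spherical position from polar angle (deg, from +z) and azimuth
# (deg, from +x anterior towards +y left); radius in mm
.sph_pos <- function(polar, azimuth, radius) {
  th <- polar * pi / 180
  ph <- azimuth * pi / 180
  radius * c(sin(th) * cos(ph), sin(th) * sin(ph), cos(th))
}

# great-circle interpolation between two points on a sphere
.slerp <- function(a, b, t) {
  ra <- sqrt(sum(a^2))
  ua <- a / ra
  ub <- b / sqrt(sum(b^2))
  omega <- acos(pmin(1, pmax(-1, sum(ua * ub))))
  if (omega < 1e-12) return(a)
  ra * (sin((1 - t) * omega) * ua + sin(t * omega) * ub) / sin(omega)
}

#' Idealized spherical montage for the 64-channel Biosemi layout
#'
#' Electrode positions are constructed on the scalp sphere from the 10-10
#' system geometry: midline electrodes at 18 degree steps along the
#' nasion-inion arc, an outer ring of 20 electrodes at 72 degrees polar
#' angle spaced 18 degrees in azimuth, interior electrodes by great-circle
#' interpolation between the midline and ring electrode of the same row,
#' and P9/P10/Iz on the 90 degree (equatorial) circle. Head frame:
#' +x anterior, +y left, +z superior, origin at the sphere centre.
#'
#' @param scalp_radius Scalp sphere radius in mm (default 85, the outer
#'   shell of [head_model()]).
#' @return A `montage` object: list with `labels` (64 channel names) and
#'   `positions` (64 x 3 matrix, mm).
#' @export
montage_biosemi64 <- function(scalp_radius = 85) {
  pos <- list()
  # midline (azimuth 0 anterior / 180 posterior)
  mid <- list(Fpz = c(72, 0), AFz = c(54, 0), Fz = c(36, 0), FCz = c(18, 0),
              Cz = c(0, 0), CPz = c(18, 180), Pz = c(36, 180),
              POz = c(54, 180), Oz = c(72, 180), Iz = c(90, 180))
  for (nm in names(mid)) {
    pos[[nm]] <- .sph_pos(mid[[nm]][1], mid[[nm]][2], scalp_radius)
  }
  # outer ring at polar 72, azimuth measured from Fpz towards the left
  ring <- c(Fp1 = 18, AF7 = 36, F7 = 54, FT7 = 72, T7 = 90, TP7 = 108,
            P7 = 126, PO7 = 144, O1 = 162)
  for (nm in names(ring)) {
    pos[[nm]] <- .sph_pos(72, ring[[nm]], scalp_radius)
    rnm <- chartr("17", "28", nm)        # left label -> right label
    pos[[rnm]] <- .sph_pos(72, -ring[[nm]], scalp_radius)
  }
  # central coronal arc
  for (i in c(1, 3, 5)) {
    pos[[paste0("C", i)]] <- .sph_pos(18 * (i + 1) / 2, 90, scalp_radius)
    pos[[paste0("C", i + 1)]] <- .sph_pos(18 * (i + 1) / 2, -90, scalp_radius)
  }
  # interior rows: interpolate midline -> ring along the great circle
  rows <- list(c("AFz", "AF7", "AF3", "0.5"),
               c("POz", "PO7", "PO3", "0.5"))
  for (r in rows) {
    pos[[r[3]]] <- .slerp(pos[[r[1]]], pos[[r[2]]], as.numeric(r[4]))
    rr <- chartr("37", "48", r[3]); ring_r <- chartr("7", "8", r[2])
    pos[[rr]] <- .slerp(pos[[r[1]]], pos[[ring_r]], as.numeric(r[4]))
  }
  quarters <- list(c("Fz", "F7", "F"), c("FCz", "FT7", "FC"),
                   c("CPz", "TP7", "CP"), c("Pz", "P7", "P"))
  for (r in quarters) {
    ring_r <- chartr("7", "8", r[2])
    for (i in 1:3) {
      t <- i / 4
      pos[[paste0(r[3], 2 * i - 1)]] <- .slerp(pos[[r[1]]], pos[[r[2]]], t)
      pos[[paste0(r[3], 2 * i)]] <- .slerp(pos[[r[1]]], pos[[ring_r]], t)
    }
  }
  pos[["P9"]] <- .sph_pos(90, 126, scalp_radius)
  pos[["P10"]] <- .sph_pos(90, -126, scalp_radius)

  labels <- biosemi64_labels()
  stopifnot(setequal(names(pos), labels))
  positions <- do.call(rbind, pos[labels])
  rownames(positions) <- labels
  montage(labels, positions)
}

#' Construct and validate a montage
#'
#' @param labels Character vector of 64 unique channel names.
#' @param positions 64 x 3 numeric matrix of electrode positions (mm, head
#'   frame: +x anterior, +y left, +z superior). All rows must lie on a
#'   common sphere around the origin.
#' @return A `montage` object.
#' @export
montage <- function(labels, positions) {
  positions <- as.matrix(positions)
  if (length(labels) != 64 || nrow(positions) != 64 || ncol(positions) != 3)
    stop("montage must have exactly 64 labelled 3-D positions")
  if (anyDuplicated(labels)) stop("montage labels must be unique")
  r <- sqrt(rowSums(positions^2))
  radius <- mean(r)
  if (any(abs(r - radius) > 1e-9 * radius))
    stop("all electrode positions must lie on the scalp sphere")
  rownames(positions) <- labels
  structure(list(labels = labels, positions = positions, radius = radius),
            class = "montage")
}

#' Read a montage from a TSV file
#'
#' Expects columns `label`, `x`, `y`, `z` (mm, head frame).
#'
#' @param path Path to the TSV file.
#' @return A `montage` object.
#' @export
read_montage <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("label", "x", "y", "z") %in% names(tab)))
  montage(tab$label, as.matrix(tab[, c("x", "y", "z")]))
}

#' Write a montage to a TSV file
#'
#' @param m A `montage` object.
#' @param path Output path.
#' @export
write_montage <- function(m, path) {
  tab <- data.frame(label = m$labels, x = m$positions[, 1],
                    y = m$positions[, 2], z = m$positions[, 3])
  utils::write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
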