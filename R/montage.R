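# Idealized spherical 10-10 montage.
#
# Electrode positions are constructed geometrically on a unit sphere
# (x = right, y = anterior, z = superior): the vertex Cz sits at the
# pole, midline electrodes step down the nasion-inion arc in 18 degree
# increments, the outer 10-10 ring lies at 72 degrees inclination in
# 18 degree azimuth steps, and intermediate electrodes are placed by
# spherical interpolation between the midline and the outer ring, the
# classic cross-arc construction of the 10-20 system.

ring_labels <- c(
  "Fpz", "Fp2", "AF8", "F8", "FT8", "T8", "TP8", "P8", "PO8", "O2",
  "Oz", "O1", "PO7", "P7", "TP7", "T7", "FT7", "F7", "AF7", "Fp1"
)
ring_azimuth <- c(0, 18, 36, 54, 72, 90, 108, 126, 144, 162,
                  180, -162, -144, -126, -108, -90, -72, -54, -36, -18)

# row definitions: midline label, inclination (deg), outer-ring azimuth,
# lateral labels ordered from midline outward (left side; right mirrors)
row_spec <- list(
  list(mid = "AFz", theta = 54, ring_az = 36, left = c("AF3"),
       right = c("AF4"), t = c(0.5)),
  list(mid = "Fz", theta = 36, ring_az = 54, left = c("F1", "F3", "F5"),
       right = c("F2", "F4", "F6"), t = c(0.25, 0.5, 0.75)),
  list(mid = "FCz", theta = 18, ring_az = 72, left = c("FC1", "FC3", "FC5"),
       right = c("FC2", "FC4", "FC6"), t = c(0.25, 0.5, 0.75)),
  list(mid = "Cz", theta = 0, ring_az = 90, left = c("C1", "C3", "C5"),
       right = c("C2", "C4", "C6"), t = c(0.25, 0.5, 0.75)),
  list(mid = "CPz", theta = -18, ring_az = 108, left = c("CP1", "CP3", "CP5"),
       right = c("CP2", "CP4", "CP6"), t = c(0.25, 0.5, 0.75)),
  list(mid = "Pz", theta = -36, ring_az = 126, left = c("P1", "P3", "P5"),
       right = c("P2", "P4", "P6"), t = c(0.25, 0.5, 0.75)),
  list(mid = "POz", theta = -54, ring_az = 144, left = c("PO3"),
       right = c("PO4"), t = c(0.5))
)

sph_point <- function(theta_deg, azim_deg) {
  th <- theta_deg * pi / 180
  az <- azim_deg * pi / 180
  c(sin(th) * sin(az), sin(th) * cos(az), cos(th))
}

slerp <- function(a, b, t) {
  om <- acos(max(-1, min(1, sum(a * b))))
  if (om < 1e-12) return(a)
  (sin((1 - t) * om) * a + sin(t * om) * b) / sin(om)
}

#' Standard 64-channel montage with EOG
#'
#' Builds the package's idealized spherical 10-10 montage: 64 EEG
#' electrodes (61 on the 10-10 grid plus Iz and the mastoids M1/M2) and
#' four electrooculogram channels (upper/lower vertical EOG, left/right
#' horizontal EOG).  Positions are unit vectors on a sphere with
#' x = right, y = anterior, z = superior; multiply by the scalp radius
#' for metric coordinates.
#'
#' @param radius scalp radius in metres used to scale positions
#'   (default 0.1).
#' @return A data frame with columns `label`, `x`, `y`, `z`, `type`
#'   (`"eeg"` or `"eog"`) and `mastoid` (logical).
#' @examples
#' m <- standard_montage()
#' subset(m, label == "Cz")
#' @export
standard_montage <- function(radius = 0.1) {
  labs <- character(0)
  pos <- matrix(numeric(0), ncol = 3)
  add <- function(label, p) {
    labs <<- c(labs, label)
    pos <<- rbind(pos, p)
  }
  for (i in seq_along(ring_labels)) {
    add(ring_labels[i], sph_point(72, ring_azimuth[i]))
  }
  for (rw in row_spec) {
    mid_az <- if (rw$theta >= 0) 0 else 180
    m <- sph_point(abs(rw$theta), mid_az)
    add(rw$mid, m)
    eL <- sph_point(72, -rw$ring_az)
    eR <- sph_point(72, rw$ring_az)
    for (k in seq_along(rw$t)) {
      add(rw$left[k], slerp(m, eL, rw$t[k]))
      add(rw$right[k], slerp(m, eR, rw$t[k]))
    }
  }
  add("Iz", sph_point(90, 180))
  add("M1", sph_point(110, -108))
  add("M2", sph_point(110, 108))
  n_eeg <- length(labs)
  # EOG electrodes sit near the eyes; positions are nominal (they are
  # never part of the source model's lead field)
  add("VEOGU", sph_point(78, -15))
  add("VEOGL", sph_point(95, -15))
  add("HEOGL", sph_point(88, -35))
  add("HEOGR", sph_point(88, 35))
  out <- data.frame(
    label = labs,
    x = pos[, 1] * radius, y = pos[, 2] * radius, z = pos[, 3] * radius,
    type = c(rep("eeg", n_eeg), rep("eog", 4L)),
    mastoid = labs %in% c("M1", "M2"),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' @noRd
eeg_labels <- function(montage) montage$label[montage$type == "eeg"]

#' @noRd
require_channels <- function(montage, labels) {
  miss <- setdiff(labels, montage$label)
  if (length(miss)) {
    stopf("montage is missing required channel(s): %s",
          paste(miss, collapse = ", "))
  }
  invisible(TRUE)
}
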