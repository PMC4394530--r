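# Analytic EEG forward solution for a three-shell concentric sphere
# and construction of the reduced source-space head model.
#
# The surface potential of a current dipole inside a layered sphere is
# expanded in spherical harmonics.  For each harmonic degree n the
# radial profile in shell k is A_k r^n + B_k r^-(n+1); matching
# potential and radial current at the shell interfaces and imposing
# zero current through the scalp yields a boundary factor c_n that
# multiplies the free-medium expansion coefficient.  The factors are
# independent of dipole position, so they are solved once per model
# (one small linear system per degree) and reused for every source.

#' Legendre polynomials and derivatives up to degree n
#' @return list(p = matrix [length(u) x n], dp = same) for degrees 1..n
#' @noRd
legendre_upto <- function(u, n) {
  m <- length(u)
  p <- matrix(0, m, n + 1L)   # columns are degrees 0..n
  dp <- matrix(0, m, n + 1L)
  p[, 1L] <- 1
  if (n >= 1) {
    p[, 2L] <- u
    dp[, 2L] <- 1
  }
  if (n >= 2) {
    for (k in 2:n) {
      p[, k + 1L] <- ((2 * k - 1) * u * p[, k] - (k - 1) * p[, k - 1L]) / k
      dp[, k + 1L] <- dp[, k - 1L] + (2 * k - 1) * p[, k]
    }
  }
  list(p = p[, -1L, drop = FALSE], dp = dp[, -1L, drop = FALSE])
}

#' Boundary factors for the layered-sphere expansion
#'
#' @param n_max highest harmonic degree.
#' @param radii shell outer radii in metres, innermost first
#'   (brain, skull, scalp).
#' @param cond conductivities (S/m) per shell, same order.
#' @return numeric vector c_n, n = 1..n_max, in radii normalized to the
#'   scalp radius.  For equal conductivities c_n = (2n+1)/n, the
#'   homogeneous-sphere value.
#' @noRd
shell_factors <- function(n_max, radii, cond) {
  ns <- length(radii)
  stopifnot(length(cond) == ns, ns >= 1)
  R <- radii[ns]
  f <- radii / R
  out <- numeric(n_max)
  if (ns == 1L) {
    n <- seq_len(n_max)
    return((2 * n + 1) / n)
  }
  for (n in seq_len(n_max)) {
    # unknowns: A_1, (A_k, B_k) for k = 2..ns ; source term s = 1 in shell 1
    nu <- 2L * ns - 1L
    M <- matrix(0, nu, nu)
    rhs <- numeric(nu)
    idxA <- function(k) if (k == 1L) 1L else 2L * (k - 1L)
    idxB <- function(k) 2L * (k - 1L) + 1L
    row <- 0L
    for (k in seq_len(ns - 1L)) {
      r <- f[k]
      # continuity of potential
      row <- row + 1L
      M[row, idxA(k)] <- r^n
      if (k > 1L) M[row, idxB(k)] <- r^(-(n + 1))
      M[row, idxA(k + 1L)] <- -r^n
      M[row, idxB(k + 1L)] <- -r^(-(n + 1))
      if (k == 1L) rhs[row] <- -r^(-(n + 1))
      # continuity of radial current density
      row <- row + 1L
      M[row, idxA(k)] <- cond[k] * n * r^(n - 1)
      if (k > 1L) M[row, idxB(k)] <- -cond[k] * (n + 1) * r^(-(n + 2))
      M[row, idxA(k + 1L)] <- -cond[k + 1L] * n * r^(n - 1)
      M[row, idxB(k + 1L)] <- cond[k + 1L] * (n + 1) * r^(-(n + 2))
      if (k == 1L) rhs[row] <- cond[1L] * (n + 1) * r^(-(n + 2))
    }
    # no current through the outer surface (r = 1)
    row <- row + 1L
    M[row, idxA(ns)] <- n
    M[row, idxB(ns)] <- -(n + 1)
    # column equilibration: powers r^n and r^-(n+1) span many orders of
    # magnitude at high degree
    cs <- apply(abs(M), 2, max)
    sol <- solve(M * rep(1 / cs, each = nu), rhs) / cs
    out[n] <- sol[idxA(ns)] + sol[idxB(ns)]
  }
  out
}

#' Scalp potential of dipoles in a three-shell spherical head
#'
#' Analytic series solution for the electric potential generated on the
#' scalp surface by current dipoles inside the innermost shell of a
#' concentric-sphere conductor.
#'
#' @param dipole_pos numeric vector of length 3 (metres, head centre at
#'   the origin) or an n x 3 matrix of dipole positions.
#' @param moment matching vector/matrix of dipole moments (A m).
#' @param sensor_pos m x 3 matrix of electrode positions; they are
#'   radially projected onto the scalp sphere.
#' @param radii outer radii of the brain, skull and scalp shells in
#'   metres (default `c(0.087, 0.092, 0.1)`).
#' @param cond shell conductivities in S/m
#'   (default `c(0.33, 0.0042, 0.33)`).
#' @param n_terms series truncation degree (default 100).
#' @return m x n matrix of potentials in volts (sensors by dipoles).
#' @examples
#' m <- standard_montage()
#' sens <- as.matrix(m[m$label %in% c("Cz", "Fz", "Pz"), c("x", "y", "z")])
#' spherical_potential(c(0, 0, 0.07), c(0, 0, 1e-8), sens)
#' @export
spherical_potential <- function(dipole_pos, moment, sensor_pos,
                                radii = c(0.087, 0.092, 0.1),
                                cond = c(0.33, 0.0042, 0.33),
                                n_terms = 100) {
  if (is.null(dim(dipole_pos))) dipole_pos <- matrix(dipole_pos, nrow = 1)
  if (is.null(dim(moment))) moment <- matrix(moment, nrow = 1)
  stopifnot(ncol(dipole_pos) == 3, ncol(moment) == 3,
            nrow(dipole_pos) == nrow(moment))
  R <- radii[length(radii)]
  b <- sqrt(rowSums(dipole_pos^2))
  if (any(b >= radii[1])) {
    stopf("dipole(s) outside the innermost shell (|r| >= %.3f m)", radii[1])
  }
  sn <- sqrt(rowSums(sensor_pos^2))
  if (any(sn <= 0)) stopf("sensor at the head centre is degenerate")
  e_hat <- sensor_pos / sn
  cn <- shell_factors(n_terms, radii, cond)
  n_seq <- seq_len(n_terms)
  V <- matrix(0, nrow(sensor_pos), nrow(dipole_pos))
  for (j in seq_len(nrow(dipole_pos))) {
    fb <- b[j] / R
    if (b[j] < 1e-12) {
      p_hat <- c(0, 0, 1)      # direction irrelevant at the centre
      q_r <- 0
      q_t <- moment[j, ]
    } else {
      p_hat <- dipole_pos[j, ] / b[j]
      q_r <- sum(moment[j, ] * p_hat)
      q_t <- moment[j, ] - q_r * p_hat
    }
    u <- as.numeric(e_hat %*% p_hat)
    leg <- legendre_upto(u, n_terms)
    et <- as.numeric(e_hat %*% q_t)
    radial <- cn * c(1, cumprod(rep(fb, n_terms - 1L)))  # c_n * fb^(n-1)
    ang <- leg$p %*% (radial * n_seq * q_r) + leg$dp %*% radial * et
    V[, j] <- ang / (4 * pi * cond[1] * R^2)
  }
  V
}

fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- pi * (1 + sqrt(5)) * i
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  out <- cbind(r * cos(phi), r * sin(phi), z)
  dimnames(out) <- NULL
  out
}

#' Build a reduced spherical head model with auditory-cortex ROIs
#'
#' Constructs the forward model used for source LDAEP analysis: a
#' quasi-uniform grid of cortical source points on a sphere inside a
#' three-shell spherical conductor, the analytic lead field for the
#' EEG montage (mastoids excluded, rows average-referenced), and two
#' lateral-temporal regions of interest that stand in for left and
#' right primary auditory cortex.
#'
#' @param n_sources number of source grid points (default 254).
#' @param montage electrode table from [standard_montage()].
#' @param source_radius radius of the source shell in metres; must lie
#'   strictly inside the innermost conductor shell (default 0.078).
#' @param radii,cond conductor geometry, see [spherical_potential()].
#' @param orientation `"radial"` for one radially oriented dipole per
#'   grid point (scalar standardization) or `"free"` for three
#'   orthogonal dipoles per point.
#' @param roi_angle angular radius (degrees) of the auditory-cortex
#'   ROI caps (default 25).
#' @param n_terms series truncation for the forward solution.
#' @return An object of class `head_model`: list with `sensors`
#'   (labels), `sensor_pos`, `source_pos`, `orientation`, `L`
#'   (average-referenced lead field, sensors x sources[x3]), `roi`
#'   (list of source index vectors `left`, `right`), `radii`, `cond`.
#' @examples
#' hm <- build_head_model(n_sources = 42)
#' dim(hm$L)
#' lengths(hm$roi)
#' @export
build_head_model <- function(n_sources = 254,
                             montage = standard_montage(),
                             source_radius = 0.078,
                             radii = c(0.087, 0.092, 0.1),
                             cond = c(0.33, 0.0042, 0.33),
                             orientation = c("radial", "free"),
                             roi_angle = 25,
                             n_terms = 100) {
  orientation <- match.arg(orientation)
  if (!is_number(n_sources) || n_sources < 2) {
    stopf("'n_sources' must be >= 2")
  }
  if (source_radius >= radii[1]) {
    stopf("degenerate geometry: source radius %.3f not inside brain shell %.3f",
          source_radius, radii[1])
  }
  use <- montage$type == "eeg" & !montage$mastoid
  sensors <- montage$label[use]
  sensor_pos <- as.matrix(montage[use, c("x", "y", "z")])
  rownames(sensor_pos) <- sensors
  grid <- fibonacci_sphere(as.integer(n_sources)) * source_radius
  # per-point dipole orientations
  if (orientation == "radial") {
    ori <- grid / source_radius
    pos_rep <- grid
  } else {
    ori <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) diag(3)))
    pos_rep <- grid[rep(seq_len(nrow(grid)), each = 3L), , drop = FALSE]
  }
  L <- spherical_potential(pos_rep, ori, sensor_pos,
                           radii = radii, cond = cond, n_terms = n_terms)
  # average reference across the retained sensors
  L <- sweep(L, 2, colMeans(L))
  dimnames(L) <- NULL
  # lateral-temporal caps around the auditory-cortex direction
  ctr_l <- c(-0.94, -0.10, 0.33)
  ctr_l <- ctr_l / sqrt(sum(ctr_l^2))
  ctr_r <- ctr_l * c(-1, 1, 1)
  dir <- grid / source_radius
  ang_l <- acos(pmin(1, pmax(-1, dir %*% ctr_l))) * 180 / pi
  ang_r <- acos(pmin(1, pmax(-1, dir %*% ctr_r))) * 180 / pi
  roi <- list(left = which(ang_l <= roi_angle), right = which(ang_r <= roi_angle))
  if (!length(roi$left) || !length(roi$right)) {
    stopf("ROI caps are empty; increase 'n_sources' or 'roi_angle'")
  }
  stopifnot(length(intersect(roi$left, roi$right)) == 0L)
  structure(
    list(sensors = sensors, sensor_pos = sensor_pos,
         source_pos = grid, orientation = orientation, L = L,
         roi = roi, radii = radii, cond = cond,
         source_radius = source_radius),
    class = "head_model"
  )
}

#' @export
print.head_model <- function(x, ...) {
  cat(sprintf(
    "Three-shell spherical head model: %d sensors, %d sources (%s orientation)\n",
    length(x$sensors), nrow(x$source_pos), x$orientation))
  cat(sprintf("ROI sizes: left %d, right %d\n",
              length(x$roi$left), length(x$roi$right)))
  invisible(x)
}
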