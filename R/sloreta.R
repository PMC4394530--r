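# Standardized minimum-norm source estimation (sLORETA-type) and
# source-space LDAEP.
#
# The minimum-norm inverse T = L' (L L' + alpha H)^+ maps sensor data
# to source current estimates; sLORETA standardizes the estimate at
# each source by the corresponding diagonal block of the resolution
# matrix T L, which gives a unitless standardized power with zero
# localization error for noiseless point sources.

#' Moore-Penrose pseudoinverse via eigendecomposition
#' @noRd
pinv_sym <- function(M, tol = 1e-10) {
  e <- eigen(M, symmetric = TRUE)
  keep <- e$values > tol * max(e$values)
  e$vectors[, keep, drop = FALSE] %*%
    (t(e$vectors[, keep, drop = FALSE]) / e$values[keep])
}

#' Compute an sLORETA inverse operator
#'
#' Builds the standardized minimum-norm transform for a head model:
#' the minimum-norm kernel regularized on the average-reference sensor
#' subspace, together with per-source standardization factors taken
#' from the diagonal (blocks) of the resolution matrix.
#'
#' @param model a [build_head_model()] object.
#' @param alpha regularization parameter (>= 0).  `NULL` (default)
#'   uses `trace(L L') / (n_sensors * snr^2)`.
#' @param snr assumed amplitude signal-to-noise ratio for the default
#'   `alpha` (default 10).
#' @return An object of class `sloreta_transform`: list with `T`
#'   (sources[x3] x sensors kernel), `standardizer` (per-source scalar,
#'   or 3x3 block inverses for free orientation), `valid` (logical per
#'   source; sources whose standardization block is numerically
#'   singular are flagged invalid rather than silently zeroed),
#'   `alpha`, and the generating `model`.
#' @examples
#' hm <- build_head_model(n_sources = 42)
#' op <- compute_sloreta_transform(hm)
#' @export
compute_sloreta_transform <- function(model, alpha = NULL, snr = 10) {
  stopifnot(inherits(model, "head_model"))
  L <- model$L
  m <- nrow(L)
  if (is.null(alpha)) alpha <- sum(L * L) / (m * snr^2)
  if (!is_number(alpha) || alpha < 0) stopf("'alpha' must be >= 0")
  H <- diag(m) - matrix(1 / m, m, m)   # average-reference projector
  M <- L %*% t(L) + alpha * H
  Minv <- pinv_sym(M)
  Tk <- t(L) %*% Minv
  R <- Tk %*% L                         # resolution matrix
  n_src <- nrow(model$source_pos)
  if (model$orientation == "radial") {
    s <- diag(R)
    valid <- s > 1e-12 * max(s)
    standardizer <- s
  } else {
    standardizer <- vector("list", n_src)
    valid <- logical(n_src)
    for (i in seq_len(n_src)) {
      idx <- (3L * (i - 1L) + 1L):(3L * i)
      blk <- R[idx, idx]
      ok <- all(is.finite(blk)) &&
        rcond(blk) > 1e-12
      valid[i] <- ok
      standardizer[[i]] <- if (ok) solve(blk) else matrix(NA_real_, 3, 3)
    }
  }
  structure(
    list(T = Tk, standardizer = standardizer, valid = valid,
         alpha = alpha, model = model),
    class = "sloreta_transform"
  )
}

#' Standardized source power for sensor data
#'
#' Applies an sLORETA transform to sensor-space data, returning
#' standardized current-density power per source and time sample.
#' Data are average-referenced before inversion, which makes the
#' output invariant to the recording reference.
#'
#' @param transform a [compute_sloreta_transform()] object.
#' @param data sensors x time numeric matrix (rows must match
#'   `transform$model$sensors`) or a vector for a single sample.
#' @param times optional time axis (ms) stored alongside.
#' @return Object of class `source_activity`: list with `power`
#'   (sources x time, invalid sources NA), `times`, `alpha`.
#' @export
source_activity <- function(transform, data, times = NULL) {
  stopifnot(inherits(transform, "sloreta_transform"))
  if (is.null(dim(data))) data <- matrix(data, ncol = 1)
  m <- length(transform$model$sensors)
  if (nrow(data) != m) {
    stopf("data has %d rows but the model has %d sensors", nrow(data), m)
  }
  data <- sweep(data, 2, colMeans(data))  # re-reference to average
  j <- transform$T %*% data
  n_src <- nrow(transform$model$source_pos)
  if (transform$model$orientation == "radial") {
    p <- j^2 / transform$standardizer
  } else {
    p <- matrix(NA_real_, n_src, ncol(data))
    for (i in seq_len(n_src)) {
      if (!transform$valid[i]) next
      idx <- (3L * (i - 1L) + 1L):(3L * i)
      ji <- j[idx, , drop = FALSE]
      p[i, ] <- colSums(ji * (transform$standardizer[[i]] %*% ji))
    }
  }
  p[!transform$valid, ] <- NA_real_
  structure(list(power = p, times = times, alpha = transform$alpha),
            class = "source_activity")
}

#' Mean standardized current density over an ROI and time window
#'
#' @param activity a [source_activity()] object with a `times` axis.
#' @param roi integer vector of source indices, or the name of an ROI
#'   in the generating model when one is attached.
#' @param window numeric length-2 window in ms (inclusive).
#' @param model optional head model used to resolve a named `roi`.
#' @return Mean standardized density (scalar).
#' @export
roi_mean_current_density <- function(activity, roi, window, model = NULL) {
  stopifnot(inherits(activity, "source_activity"))
  if (is.character(roi)) {
    if (is.null(model)) stopf("a 'model' is required to resolve ROI '%s'", roi)
    if (!roi %in% names(model$roi)) stopf("unknown ROI '%s'", roi)
    roi <- model$roi[[roi]]
  }
  if (!length(roi)) stopf("empty ROI")
  if (is.null(activity$times)) stopf("activity has no time axis")
  sel <- activity$times >= window[1] & activity$times <= window[2]
  if (!any(sel)) stopf("window [%g, %g] ms contains no samples",
                       window[1], window[2])
  mean(activity$power[roi, sel, drop = FALSE])
}

#' Source-space LDAEP from per-intensity evoked responses
#'
#' Inverts each intensity's averaged evoked response, averages the
#' standardized current density over the left and right
#' auditory-cortex ROIs in three analysis windows (the N1 window, the
#' P2 window, and the broad 60-240 ms window), and fits the LDAEP
#' slope of ROI density on stimulus intensity for the left ROI, right
#' ROI, and the mean of the two hemisphere series.
#'
#' @param evoked an `evoked_set` from [average_by_intensity()].
#' @param model a [build_head_model()] object.
#' @param alpha regularization passed to [compute_sloreta_transform()].
#' @param windows named list of ms windows (defaults: `n1`
#'   c(80, 130), `p2` c(130, 230), `broad` c(60, 240)).
#' @return Object of class `source_ldaep`: list with `slopes` (data
#'   frame window x left/right/avg), `roi_means` (per intensity),
#'   `fits` (the underlying [ldaep()] objects), `alpha`.
#' @export
compute_source_ldaep <- function(evoked, model, alpha = NULL,
                                 windows = list(n1 = c(80, 130),
                                                p2 = c(130, 230),
                                                broad = c(60, 240))) {
  stopifnot(inherits(evoked, "evoked_set"), inherits(model, "head_model"))
  intensities <- evoked$intensities
  if (length(intensities) < 2) stopf("need >= 2 intensities")
  tr <- compute_sloreta_transform(model, alpha = alpha)
  idx <- match(model$sensors, evoked$channels)
  if (anyNA(idx)) {
    stopf("evoked set lacks model sensor(s): %s",
          paste(model$sensors[is.na(idx)], collapse = ", "))
  }
  res <- list()
  for (i in seq_along(intensities)) {
    act <- source_activity(tr, evoked$data[[i]][idx, , drop = FALSE],
                           times = evoked$times)
    for (w in names(windows)) {
      res[[length(res) + 1L]] <- data.frame(
        intensity = intensities[i], window = w,
        left = roi_mean_current_density(act, model$roi$left, windows[[w]]),
        right = roi_mean_current_density(act, model$roi$right, windows[[w]])
      )
    }
  }
  roi_means <- do.call(rbind, res)
  roi_means$avg <- (roi_means$left + roi_means$right) / 2
  fits <- list()
  slopes <- data.frame(window = names(windows), left = NA_real_,
                       right = NA_real_, avg = NA_real_)
  for (k in seq_along(windows)) {
    w <- names(windows)[k]
    sub <- roi_means[roi_means$window == w, ]
    for (side in c("left", "right", "avg")) {
      fit <- ldaep(sub[[side]], sub$intensity)
      fits[[paste(w, side, sep = "_")]] <- fit
      slopes[k, side] <- coef(fit)[["slope"]]
    }
  }
  structure(list(slopes = slopes, roi_means = roi_means, fits = fits,
                 alpha = tr$alpha, windows = windows),
            class = "source_ldaep")
}

#' @export
print.source_ldaep <- function(x, ...) {
  cat("Source LDAEP slopes (standardized density / dB):\n")
  print(x$slopes, row.names = FALSE)
  invisible(x)
}
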