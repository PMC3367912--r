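# Depth-weighted minimum-norm inverse with loose orientation constraint:
# W = R A^T (A R A^T + lambda^2 C)^-1, applied as s(t) = W x(t), plus
# noise-covariance estimation and sign-aligned ROI time-course extraction.

#' Estimate the sensor noise covariance from raw session data
#'
#' By default uses Passive-block samples excluding -0.1 to 1.0 s around every
#' sound onset, i.e. periods with the least stimulus-driven structure, then
#' symmetrizes the empirical covariance and adds diagonal loading of
#' \code{loading_fraction} times the mean diagonal.
#'
#' @param session a \code{sensor_session}.
#' @param segment_selector NULL (default rule), a logical vector over
#'   samples, or a function(session) returning sample indices.
#' @param loading_fraction nonnegative diagonal loading fraction
#'   (default 0.05).
#' @return object of class \code{noise_covariance}: \code{entries},
#'   \code{n_samples_used}, \code{regularization_loading}.
#' @export
estimate_noise_covariance <- function(session, segment_selector = NULL,
                                      loading_fraction = 0.05) {
  if (loading_fraction < 0) config_error("loading_fraction must be nonnegative")
  X <- session$sensors
  ns <- nrow(X); n <- ncol(X); fs <- session$fs
  if (is.null(segment_selector)) {
    keep <- rep(FALSE, n)
    bl <- session$schedule$blocks
    for (b in which(bl$condition == "passive")) {
      i0 <- floor(bl$start_s[b] * fs) + 1L
      i1 <- min(n, floor(bl$end_s[b] * fs))
      keep[i0:i1] <- TRUE
    }
    onsets <- as.vector(outer(session$schedule$events$onset_s,
                              session$schedule$sound_offsets_s, "+"))
    for (t0 in onsets) {
      i0 <- max(1L, floor((t0 - 0.1) * fs) + 1L)
      i1 <- min(n, floor((t0 + 1.0) * fs))
      if (i0 <= i1) keep[i0:i1] <- FALSE
    }
    idx <- which(keep)
  } else if (is.logical(segment_selector)) {
    idx <- which(segment_selector)
  } else if (is.function(segment_selector)) {
    idx <- segment_selector(session)
  } else {
    idx <- as.integer(segment_selector)
  }
  if (length(idx) < 10 * ns)
    estimation_error("too few samples for covariance estimation: %d < 10 x %d sensors",
                     length(idx), ns)
  Xs <- X[, idx, drop = FALSE]
  if (any(!is.finite(Xs))) data_error("non-finite sensor data in selected segments")
  Xc <- Xs - rowMeans(Xs)
  C <- tcrossprod(Xc) / (length(idx) - 1)
  C <- (C + t(C)) / 2
  load <- loading_fraction * mean(diag(C))
  C <- C + diag(load, ns)
  ok <- tryCatch({ chol(C); TRUE }, error = function(e) FALSE)
  if (!ok) estimation_error("estimated noise covariance is not positive definite (rank-deficient data and zero loading?)")
  structure(list(entries = C, n_samples_used = length(idx),
                 regularization_loading = load),
            class = "noise_covariance")
}

# Orthonormal per-vertex orientation basis [normal, tangent1, tangent2].
orientation_basis <- function(normal) {
  a <- if (abs(normal[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  t1 <- c(a[2] * normal[3] - a[3] * normal[2],
          a[3] * normal[1] - a[1] * normal[3],
          a[1] * normal[2] - a[2] * normal[1])
  t1 <- t1 / sqrt(sum(t1^2))
  t2 <- c(normal[2] * t1[3] - normal[3] * t1[2],
          normal[3] * t1[1] - normal[1] * t1[3],
          normal[1] * t1[2] - normal[2] * t1[1])
  cbind(normal, t1, t2, deparse.level = 0)
}

#' Build the depth-weighted loose-orientation source covariance
#'
#' Diagonal source covariance in per-vertex surface coordinates (normal and
#' two tangential components). The per-vertex weight is proportional to the
#' gain-column norm to the power -2*depth_exponent, compensating the bias of
#' minimum-norm solutions toward superficial (strong-gain) sources;
#' tangential components are scaled by \code{loose_factor}. Globally
#' normalized so the mean diagonal entry is 1.
#'
#' @param mesh \code{cortical_mesh}.
#' @param gain \code{gain_matrix}.
#' @param depth_exponent real in [0, 1]; default 0.8.
#' @param loose_factor real in (0, 1]; default 0.6.
#' @return object of class \code{source_covariance}: \code{diag} (length
#'   3*vertices, ordered normal, t1, t2 per vertex), \code{basis} (3 x 3 x
#'   vertices), \code{depth_exponent}, \code{loose_factor}.
#' @export
build_source_covariance <- function(mesh, gain, depth_exponent = 0.8,
                                    loose_factor = 0.6) {
  if (depth_exponent < 0 || depth_exponent > 1)
    config_error("depth_exponent must be in [0, 1]")
  if (loose_factor <= 0 || loose_factor > 1)
    config_error("loose_factor must be in (0, 1]")
  nv <- mesh$n_vertices
  w <- numeric(nv)
  for (v in seq_len(nv)) {
    cn <- sqrt(sum(gain_block(gain, v)^2))
    if (cn <= 0) data_error("zero gain column at vertex %d", v)
    w[v] <- cn^(-2 * depth_exponent)
  }
  d <- as.vector(rbind(w, loose_factor * w, loose_factor * w))
  d <- d / mean(d)
  basis <- array(0, c(3, 3, nv))
  for (v in seq_len(nv)) basis[, , v] <- orientation_basis(mesh$normals[v, ])
  structure(list(diag = d, basis = basis, depth_exponent = depth_exponent,
                 loose_factor = loose_factor),
            class = "source_covariance")
}

# Rotate the Cartesian gain into per-vertex surface coordinates.
rotate_gain <- function(A, basis) {
  nv <- dim(basis)[3]
  out <- matrix(0, nrow(A), 3L * nv)
  for (v in seq_len(nv)) {
    cols <- (3 * v - 2):(3 * v)
    out[, cols] <- A[, cols, drop = FALSE] %*% basis[, , v]
  }
  out
}

#' Assemble the minimum-norm inverse operator
#'
#' Computes \code{W = R A^T (A R A^T + lambda^2 C)^-1} with
#' \code{lambda^2 = 1/snr^2} via a Cholesky factorization of the symmetric
#' sensor-space matrix (never an unfactorized explicit inverse).
#' \code{snr = Inf} sets \code{lambda^2 = 1}, i.e. the unregularized textbook
#' form in which the noise covariance enters with unit weight.
#'
#' @param gain \code{gain_matrix} or a plain sensors x components matrix.
#' @param noise_cov \code{noise_covariance} or a plain SPD matrix.
#' @param source_cov \code{source_covariance}, or a plain numeric vector of
#'   diagonal entries (then no orientation rotation is applied and
#'   normal-component extraction is unavailable).
#' @param snr assumed amplitude signal-to-noise ratio (> 0); default 3
#'   (lambda^2 = 1/9), the conventional minimum-norm default.
#' @return object of class \code{inverse_operator}: \code{entries}
#'   ((3*vertices) x sensors in surface coordinates when a basis is present),
#'   \code{basis}, \code{lambda2}, \code{snr}, and provenance dimensions.
#' @export
make_inverse_operator <- function(gain, noise_cov, source_cov, snr = 3) {
  A <- if (inherits(gain, "gain_matrix")) gain$entries else as.matrix(gain)
  C <- if (inherits(noise_cov, "noise_covariance")) noise_cov$entries else as.matrix(noise_cov)
  if (inherits(source_cov, "source_covariance")) {
    r <- source_cov$diag
    basis <- source_cov$basis
    A <- rotate_gain(A, basis)
  } else {
    r <- as.numeric(source_cov)
    basis <- NULL
  }
  if (ncol(A) != length(r)) data_error("gain columns (%d) do not match source covariance length (%d)",
                                       ncol(A), length(r))
  if (nrow(C) != nrow(A)) data_error("noise covariance dimension does not match sensor count")
  if (!is_scalar_num(snr) && !identical(snr, Inf)) config_error("snr must be a positive scalar")
  if (snr <= 0) config_error("snr must be positive")
  lambda2 <- if (is.infinite(snr)) 1 else 1 / snr^2
  Ar <- sweep(A, 2, r, "*")           # A R
  M <- tcrossprod(Ar, A) + lambda2 * C
  M <- (M + t(M)) / 2
  ch <- tryCatch(chol(M), error = function(e)
    numerical_error("(A R A^T + lambda^2 C) is singular; log10 condition ~ %.1f",
                    log10(kappa(M))))
  Minv <- chol2inv(ch)
  W <- t(Ar) %*% Minv
  structure(list(entries = W, basis = basis, lambda2 = lambda2, snr = snr,
                 n_sensors = nrow(A), n_components = ncol(A)),
            class = "inverse_operator")
}

#' @export
print.inverse_operator <- function(x, ...) {
  cat(sprintf("inverse_operator: %d source components x %d sensors (lambda^2 = %.4g)\n",
              x$n_components, x$n_sensors, x$lambda2))
  invisible(x)
}

#' Apply the inverse operator to sensor data
#'
#' \code{s(t) = W x(t)} per sample. With \code{component = "normal"} the
#' surface-normal component (the first surface coordinate of each vertex) is
#' returned, one row per vertex.
#'
#' @param operator \code{inverse_operator}.
#' @param sensor_series sensors x samples matrix (or a vector, one sample per
#'   sensor).
#' @param component "all" (3 components per vertex, surface coordinates) or
#'   "normal".
#' @return components x samples matrix.
#' @export
apply_inverse <- function(operator, sensor_series, component = c("all", "normal")) {
  component <- match.arg(component)
  x <- if (is.matrix(sensor_series)) sensor_series else matrix(sensor_series, ncol = 1)
  if (nrow(x) != operator$n_sensors)
    data_error("sensor dimension %d does not match operator (%d sensors)",
               nrow(x), operator$n_sensors)
  if (component == "normal") {
    if (is.null(operator$basis))
      config_error("operator built without an orientation basis; normal component unavailable")
    idx <- seq(1L, operator$n_components, by = 3L)
    operator$entries[idx, , drop = FALSE] %*% x
  } else {
    operator$entries %*% x
  }
}

#' Sign-aligned ROI time course
#'
#' Averages surface-normal source waveforms over an ROI after multiplying
#' each vertex's waveform by the sign of the dot product between its normal
#' and the ROI's dominant orientation direction, so that opposing-wall
#' sources do not phase-cancel. The reference direction is the principal
#' eigenvector of the orientation tensor \code{sum(n n^T)} with a canonical
#' sign (largest-magnitude component positive), which for an oriented patch
#' coincides with the mean-normal direction but is invariant to per-vertex
#' sign flips of the normals. A zero dot product resolves to +1.
#'
#' @param normal_series vertices x samples matrix of normal-component source
#'   estimates (whole mesh).
#' @param mesh \code{cortical_mesh}.
#' @param roi ROI name.
#' @param hemisphere "left", "right", or NULL (both; averaged per hemisphere
#'   membership jointly).
#' @return numeric vector, one value per sample.
#' @export
# Sign-flip weights for a set of vertex normals: sign of the dot product
# with the principal orientation direction (canonical sign).
roi_sign_flips <- function(normals) {
  M <- crossprod(normals)
  ref <- eigen(M, symmetric = TRUE)$vectors[, 1]
  lead <- which.max(abs(ref))
  if (ref[lead] < 0) ref <- -ref
  fl <- sign(normals %*% ref)
  fl[fl == 0] <- 1
  as.vector(fl)
}

roi_timecourse <- function(normal_series, mesh, roi, hemisphere = NULL) {
  sel <- mesh$roi == roi
  if (!is.null(hemisphere)) sel <- sel & mesh$hemisphere == hemisphere
  verts <- which(sel)
  if (!length(verts)) config_error("ROI '%s'%s is empty", roi,
                                   if (is.null(hemisphere)) "" else paste0(" (", hemisphere, ")"))
  flips <- roi_sign_flips(mesh$normals[verts, , drop = FALSE])
  as.vector(crossprod(normal_series[verts, , drop = FALSE], flips)) / length(verts)
}
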