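# Synthetic lead field: a smooth, distance-decaying sensor sensitivity model
# standing in for a boundary-element forward solution. Each vertex contributes
# three columns (x/y/z dipole orientation); sensors sit on a spherical shell
# above the cortical patches.

#' Compute a synthetic gain (lead-field) matrix
#'
#' Sensor i responds to a dipole with moment e at position q as
#' \code{s_i * (p_i - q) . e / (|p_i - q|^2 + smoothness^2)^((k+1)/2)} with
#' falloff exponent k = 2, so a dipole's column norm decays as distance^-k and
#' nearby sources have strongly correlated columns. Sensors are placed on a
#' 90 mm shell over the mean outward direction of the mesh with seeded
#' per-sensor gain jitter. Columns are globally rescaled to mean column norm 1;
#' the condition number is recorded in attributes.
#'
#' @param mesh a \code{cortical_mesh}.
#' @param n_sensors integer >= 8.
#' @param smoothness nonnegative spatial smoothing length (mm); larger values
#'   give smoother, more correlated sensitivity profiles. Default 10.
#' @param seed integer; result is bit-identical for a fixed seed.
#' @param falloff distance falloff exponent (>= 2). Default 2.
#' @return object of class \code{gain_matrix}: \code{entries} (sensors x
#'   3*vertices), \code{sensor_positions}, \code{n_sensors},
#'   \code{n_vertices}; attribute \code{log10_condition}.
#' @export
compute_gain <- function(mesh, n_sensors, smoothness = 10, seed = 1L, falloff = 2) {
  if (!is_scalar_num(n_sensors) || n_sensors < 8)
    config_error("n_sensors must be >= 8 (got %s)", n_sensors)
  if (!is_scalar_num(smoothness) || smoothness < 0)
    config_error("smoothness must be a nonnegative real")
  if (falloff < 2) config_error("falloff exponent must be >= 2")
  n_sensors <- as.integer(n_sensors)

  up <- colMeans(mesh$normals)
  up <- up / sqrt(sum(up^2))
  rot <- rotation_to(up)
  # Fibonacci lattice on a cap of ~1.5 rad half-angle around the mean direction
  i <- seq_len(n_sensors)
  golden <- pi * (3 - sqrt(5))
  cosmax <- cos(1.5)
  z <- 1 - (i - 0.5) / n_sensors * (1 - cosmax)
  th <- golden * i
  r_shell <- 90  # mm
  dirs <- cbind(sqrt(1 - z^2) * cos(th), sqrt(1 - z^2) * sin(th), z)
  sensor_pos <- t(rot %*% t(dirs)) * r_shell
  sensor_gain <- with_seed(derive_seed(seed, "sensor_gain"),
                           exp(stats::rnorm(n_sensors, 0, 0.1)))

  nv <- mesh$n_vertices
  A <- matrix(0, n_sensors, 3L * nv)
  for (v in seq_len(nv)) {
    d <- sweep(sensor_pos, 2, mesh$positions[v, ])     # p_i - q_v
    r2 <- rowSums(d^2) + smoothness^2
    w <- sensor_gain / r2^((falloff + 1) / 2)
    A[, (3 * v - 2):(3 * v)] <- d * w
  }
  cn <- sqrt(colSums(A^2))
  if (any(!is.finite(A))) data_error("non-finite gain entries")
  if (any(cn <= 0)) data_error("gain has an all-zero column")
  norm_scale <- mean(cn)
  A <- A / norm_scale
  sv <- svd(A, nu = 0, nv = 0)$d
  structure(list(entries = A, sensor_positions = sensor_pos,
                 sensor_gains = sensor_gain, norm_scale = norm_scale,
                 n_sensors = n_sensors, n_vertices = nv,
                 smoothness = smoothness, falloff = falloff,
                 seed = as.integer(seed)),
            class = "gain_matrix",
            log10_condition = log10(max(sv) / max(min(sv), .Machine$double.eps)))
}

#' @export
print.gain_matrix <- function(x, ...) {
  cat(sprintf("gain_matrix: %d sensors x %d vertices x 3 orientations (log10 cond %.2f)\n",
              x$n_sensors, x$n_vertices, attr(x, "log10_condition")))
  invisible(x)
}

# Gain columns for one vertex (sensors x 3).
gain_block <- function(gain, v) gain$entries[, (3 * v - 2):(3 * v), drop = FALSE]

# Collapse the lead field to surface-normal orientation: sensors x vertices.
gain_normal <- function(gain, mesh) {
  nv <- mesh$n_vertices
  G <- matrix(0, gain$n_sensors, nv)
  for (v in seq_len(nv)) G[, v] <- gain_block(gain, v) %*% mesh$normals[v, ]
  G
}

#' Perturb a gain matrix to emulate a new subject's forward model
#'
#' Applies independent multiplicative Gaussian jitter to every entry,
#' emulating between-subject differences in head geometry and coregistration.
#'
#' @param gain a \code{gain_matrix}.
#' @param sd standard deviation of the multiplicative jitter (default 0.05).
#' @param seed integer seed.
#' @return a perturbed \code{gain_matrix}.
#' @export
perturb_gain <- function(gain, sd = 0.05, seed = 1L) {
  J <- with_seed(seed, matrix(stats::rnorm(length(gain$entries), 1, sd),
                              nrow(gain$entries)))
  gain$entries <- gain$entries * J
  gain
}
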