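# Synthetic MEG sessions for the auditory "what" vs "where" attention
# paradigm: block/event scheduling, 1/f cortical background, planted
# condition-dependent alpha-band sources, stimulus-locked evoked transients,
# correlated sensor noise, and EOG blink artifacts.

#' Default paradigm parameters
#'
#' Interleaved 60 s Attend-Phoneme and 60 s Attend-Location blocks with 30 s
#' Passive blocks; sound pairs of two 300 ms sounds separated by a 250 ms
#' gap, presented every 3.4 s.
#'
#' @param n_block_cycles number of (phoneme, passive, location, passive)
#'   block cycles; default 2 (360 s session, 34 pairs per attend condition).
#' @return a list of paradigm parameters.
#' @export
default_paradigm <- function(n_block_cycles = 2L) {
  list(attend_block_s = 60, passive_block_s = 30,
       inter_pair_s = 3.4, sound_duration_s = 0.3, gap_s = 0.25,
       first_pair_offset_s = 1.0, post_margin_s = 1.75,
       n_block_cycles = n_block_cycles)
}

#' Build the block and sound-pair event schedule
#'
#' Blocks follow the cycle (Attend Phoneme 60 s, Passive 30 s, Attend
#' Location 60 s, Passive 30 s). Within each block the first pair starts
#' \code{first_pair_offset_s} after block onset and subsequent pairs follow
#' every \code{inter_pair_s}; pairs are truncated so that a full post-onset
#' analysis window (\code{post_margin_s}) still fits inside the block. The
#' second sound of a pair starts \code{sound_duration_s + gap_s} after pair
#' onset (0.55 s at defaults).
#'
#' @param config list of paradigm parameters, see [default_paradigm()].
#' @param seed integer (kept for interface symmetry; the schedule is
#'   deterministic).
#' @return object of class \code{event_schedule}: \code{events} data frame
#'   (onset_s, condition, block_id), \code{blocks} data frame (start_s,
#'   end_s, condition), \code{sound_offsets_s}, \code{duration_s}.
#' @export
make_event_schedule <- function(config = default_paradigm(), seed = 1L) {
  p <- utils::modifyList(default_paradigm(), config)
  pair_span <- 2 * p$sound_duration_s + p$gap_s
  if (p$inter_pair_s <= 0 || p$attend_block_s <= 0 || p$passive_block_s <= 0)
    config_error("block durations and inter-pair interval must be positive")
  if (pair_span >= p$inter_pair_s)
    config_error("pair span %.3f s must be shorter than the inter-pair interval %.3f s",
                 pair_span, p$inter_pair_s)
  cond_cycle <- c("attend_phoneme", "passive", "attend_location", "passive")
  dur_cycle <- c(p$attend_block_s, p$passive_block_s, p$attend_block_s, p$passive_block_s)
  conds <- rep(cond_cycle, p$n_block_cycles)
  durs <- rep(dur_cycle, p$n_block_cycles)
  starts <- cumsum(c(0, durs[-length(durs)]))
  blocks <- data.frame(block_id = seq_along(conds), start_s = starts,
                       end_s = starts + durs, condition = conds,
                       stringsAsFactors = FALSE)
  ev <- do.call(rbind, lapply(seq_len(nrow(blocks)), function(b) {
    t0 <- blocks$start_s[b] + p$first_pair_offset_s
    last_ok <- blocks$end_s[b] - p$post_margin_s
    if (t0 > last_ok) return(NULL)
    onsets <- seq(t0, last_ok, by = p$inter_pair_s)
    data.frame(onset_s = onsets, condition = blocks$condition[b],
               block_id = blocks$block_id[b], stringsAsFactors = FALSE)
  }))
  structure(list(events = ev, blocks = blocks,
                 sound_offsets_s = c(0, p$sound_duration_s + p$gap_s),
                 duration_s = sum(durs), params = p),
            class = "event_schedule")
}

#' @export
print.event_schedule <- function(x, ...) {
  tab <- table(x$events$condition)
  cat(sprintf("event_schedule: %.0f s, %d pairs (%s)\n", x$duration_s,
              nrow(x$events),
              paste(names(tab), tab, sep = "=", collapse = ", ")))
  invisible(x)
}

#' Write / read the event table as tab-delimited text
#'
#' Columns onset_s (6 decimals), condition, block_id, with a header row.
#' @param schedule an \code{event_schedule}.
#' @param path output path.
#' @export
write_event_table <- function(schedule, path) {
  ev <- schedule$events
  ev$onset_s <- sprintf("%.6f", ev$onset_s)
  utils::write.table(ev, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(schedule)
}

#' @rdname write_event_table
#' @export
read_event_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Default simulation ground truth
#'
#' Encodes the planted hypothesis: stronger alpha (7-13 Hz) source power in
#' designated visual ROIs during Attend Phoneme than Attend Location, with
#' the Passive condition in between (geometric mean). \code{power_ratio} is
#' the ratio of total in-band source variance, boosted vs reference
#' condition.
#'
#' @param planted_rois ROI names carrying the alpha effect.
#' @param power_ratio linear variance ratio (boosted / reference), > 0.
#' @param effect_band numeric length 2, Hz, inside 4..80.
#' @param evoked_amplitude peak amplitude of the stimulus-locked transient
#'   (source units; 0 disables it).
#' @param alpha_snr planted oscillation in-band variance relative to the
#'   background's in-band variance in the reference condition (default 4:
#'   strong posterior alpha).
#' @param artifact_frac fraction of pairs contaminated by synthetic blinks
#'   (ignored when \code{artifact_epochs} is given).
#' @param artifact_epochs explicit pair indices to contaminate, or NULL.
#' @param subject_effect_sd per-subject lognormal jitter of the power ratio.
#' @return a list of class \code{simulation_truth}.
#' @export
default_truth <- function(planted_rois = c("pericalcarine", "lingual"),
                          power_ratio = 2,
                          effect_band = c(7, 13),
                          evoked_amplitude = 2,
                          alpha_snr = 4,
                          artifact_frac = 0.08,
                          artifact_epochs = NULL,
                          subject_effect_sd = 0.1) {
  if (power_ratio <= 0) config_error("power_ratio must be > 0")
  if (effect_band[1] < 4 || effect_band[2] > 80 || effect_band[1] > effect_band[2])
    config_error("effect_band must lie within [4, 80] Hz")
  structure(list(planted_rois = planted_rois, power_ratio = power_ratio,
                 effect_band = effect_band, evoked_amplitude = evoked_amplitude,
                 evoked_rois = "superior_temporal",
                 boosted_condition = "attend_phoneme",
                 reference_condition = "attend_location",
                 alpha_snr = alpha_snr, artifact_frac = artifact_frac,
                 artifact_epochs = artifact_epochs,
                 subject_effect_sd = subject_effect_sd,
                 background_exponent = 1, sign = 1),
            class = "simulation_truth")
}

#' Default sensor-noise covariance specification
#'
#' AR(1)-structured spatial correlation: C_ij = sigma^2 * rho^|i-j|.
#' @param sigma marginal noise standard deviation (sensor units).
#' @param rho neighbor correlation in sensor index order.
#' @export
default_noise_spec <- function(sigma = 1, rho = 0.3) list(sigma = sigma, rho = rho)

noise_covariance_matrix <- function(spec, n_sensors) {
  if (is.matrix(spec)) {
    C <- spec
  } else {
    C <- spec$sigma^2 * spec$rho^abs(outer(seq_len(n_sensors), seq_len(n_sensors), "-"))
  }
  if (nrow(C) != n_sensors || !isSymmetric(unname(C), tol = 1e-10))
    data_error("noise covariance spec is not a symmetric %d x %d matrix", n_sensors, n_sensors)
  ok <- tryCatch({ chol(C); TRUE }, error = function(e) FALSE)
  if (!ok) data_error("noise covariance spec is not positive definite")
  unname(C)
}

# Spectrally shaped real Gaussian noise, length n, sampling rate fs.
# amp_fun(f) gives the (two-sided) amplitude profile; output is scaled so the
# EXPECTED variance is var_target (deterministic scaling, not realized-sample
# normalization). Returns the series plus the expected variance in `band`.
shaped_noise <- function(n, fs, amp_fun, var_target = 1) {
  f <- c(seq(0, floor(n / 2)), seq(-ceiling(n / 2) + 1, -1)) * fs / n
  amp <- amp_fun(abs(f))
  amp[1] <- 0  # no DC
  expected_var <- sum(amp^2) / n
  if (expected_var <= 0) data_error("degenerate spectral amplitude profile")
  scale <- sqrt(var_target / expected_var)
  w <- stats::rnorm(n)
  x <- Re(stats::fft(stats::fft(w) * amp, inverse = TRUE)) / n
  list(x = x * scale, amp = amp * scale, f = f)
}

# Expected variance contributed by |f| in [lo, hi] for a shaped-noise spec.
shaped_band_variance <- function(amp, f, n, lo, hi) {
  sel <- abs(f) >= lo & abs(f) <= hi
  sum(amp[sel]^2) / n
}

one_over_f_amp <- function(exponent, f_floor = 1) {
  function(f) {
    ff <- pmax(f, f_floor)
    ifelse(f == 0, 0, ff^(-exponent / 2))
  }
}

bandpass_amp <- function(lo, hi, edge = 0.5) {
  function(f) {
    core <- as.numeric(f >= lo & f <= hi)
    rise <- f > lo - edge & f < lo
    fall <- f > hi & f < hi + edge
    core[rise] <- 0.5 * (1 + cos(pi * (lo - f[rise]) / edge))
    core[fall] <- 0.5 * (1 + cos(pi * (f[fall] - hi) / edge))
    core
  }
}

# Damped-sinusoid evoked template (identical across trials).
evoked_template <- function(fs, amplitude, f0 = 10, tau = 0.08, dur = 0.4) {
  t <- seq(0, dur, by = 1 / fs)
  amplitude * sin(2 * pi * f0 * t) * exp(-t / tau)
}

# 400 ms raised-cosine blink pulse (baseline-to-peak = peak).
blink_template <- function(fs, peak = 170, dur = 0.4) {
  t <- seq(0, dur, by = 1 / fs)
  peak * 0.5 * (1 - cos(2 * pi * t / dur))
}

add_at <- function(x, start_idx, template) {
  idx <- start_idx + seq_along(template) - 1L
  keep <- idx >= 1L & idx <= length(x)
  x[idx[keep]] <- x[idx[keep]] + template[keep]
  x
}

#' Generate one synthetic MEG session
#'
#' Source activity is 1/f background at every vertex plus, in the planted
#' ROIs, a shared narrowband (band-passed white noise) alpha component whose
#' total in-band variance is \code{power_ratio} times larger during the
#' boosted condition than during the reference condition (Passive sits at the
#' geometric mean), plus a damped-sinusoid evoked transient time-locked to
#' each sound onset in auditory ROIs. Dipoles are oriented along the surface
#' normal. Sensors are \code{gain x sources} plus correlated Gaussian noise
#' with the specified covariance, plus a frontal-pattern blink projection.
#' The EOG channel carries Gaussian noise (sigma 5 uV) and 400 ms
#' raised-cosine blinks exceeding 100 uV peak-to-peak in the designated
#' artifact epochs; all other epochs stay below 50 uV.
#'
#' @param mesh \code{cortical_mesh}.
#' @param gain \code{gain_matrix} for the same mesh.
#' @param schedule \code{event_schedule}.
#' @param truth \code{simulation_truth}, see [default_truth()].
#' @param noise_spec noise covariance spec ([default_noise_spec()] or an
#'   explicit SPD matrix).
#' @param seed integer; sessions are bit-identical for a fixed seed.
#' @param fs sampling rate, Hz (>= 160; default 300).
#' @param subject_id identifier stored with the session.
#' @param return_sources if TRUE, keep the vertex source matrix and the
#'   planted alpha component in the result (memory heavy; for diagnostics).
#' @param signal_scale global multiplier on brain sources (0 gives a
#'   noise-only session for covariance checks).
#' @return object of class \code{sensor_session}: \code{sensors} (sensors x
#'   samples), \code{eog} (uV), \code{fs}, \code{schedule},
#'   \code{truth} (with realized per-subject values), \code{subject_id},
#'   \code{noise_cov_true}.
#' @export
generate_session <- function(mesh, gain, schedule, truth = default_truth(),
                             noise_spec = default_noise_spec(), seed = 1L,
                             fs = 300, subject_id = "s01",
                             return_sources = FALSE, signal_scale = 1) {
  if (fs < 160) config_error("sampling rate must be >= 160 Hz (Nyquist-safe for 80 Hz)")
  missing_roi <- setdiff(truth$planted_rois, unique(mesh$roi))
  if (length(missing_roi))
    config_error("planted ROI(s) absent from mesh: %s", paste(missing_roi, collapse = ", "))
  n <- round(schedule$duration_s * fs)
  nv <- mesh$n_vertices
  ns <- gain$n_sensors
  C <- noise_covariance_matrix(noise_spec, ns)

  # per-subject effect jitter
  r_subj <- with_seed(derive_seed(seed, "effect"),
                      truth$power_ratio * exp(stats::rnorm(1, 0, truth$subject_effect_sd)))

  # --- background sources (normal orientation), vertices x samples ---
  amp_fun <- one_over_f_amp(truth$background_exponent)
  S <- with_seed(derive_seed(seed, "background"), {
    f <- c(seq(0, floor(n / 2)), seq(-ceiling(n / 2) + 1, -1)) * fs / n
    amp <- amp_fun(abs(f)); amp[1] <- 0
    amp <- amp * sqrt(n / sum(amp^2))  # unit expected variance per vertex
    out <- matrix(0, nv, n)
    for (v in seq_len(nv))
      out[v, ] <- Re(stats::fft(stats::fft(stats::rnorm(n)) * amp,
                                inverse = TRUE)) / n
    out
  })
  f_axis <- c(seq(0, floor(n / 2)), seq(-ceiling(n / 2) + 1, -1)) * fs / n
  amp_bg <- amp_fun(abs(f_axis)); amp_bg[1] <- 0
  amp_bg <- amp_bg * sqrt(n / sum(amp_bg^2))
  var_bg_band <- shaped_band_variance(amp_bg, f_axis, n,
                                      truth$effect_band[1], truth$effect_band[2])

  # --- planted alpha component: total in-band variance ratio == power_ratio ---
  # reference-condition oscillation variance v_base; boosted condition absorbs
  # the background's in-band power so (bg + v_boost)/(bg + v_base) = r exactly.
  v_base <- truth$alpha_snr * var_bg_band
  v_boost <- r_subj * v_base + (r_subj - 1) * var_bg_band
  v_pass <- sqrt(r_subj) * (var_bg_band + v_base) - var_bg_band
  v_cond <- c(attend_phoneme = v_boost, attend_location = v_base, passive = v_pass)
  if (truth$boosted_condition == "attend_location")
    v_cond[c("attend_phoneme", "attend_location")] <-
      v_cond[c("attend_location", "attend_phoneme")]

  gvec <- numeric(n)  # per-sample oscillation amplitude gain
  for (b in seq_len(nrow(schedule$blocks))) {
    i0 <- floor(schedule$blocks$start_s[b] * fs) + 1L
    i1 <- min(n, floor(schedule$blocks$end_s[b] * fs))
    gvec[i0:i1] <- sqrt(max(v_cond[[schedule$blocks$condition[b]]], 0))
  }

  planted_units <- list()
  for (rn in truth$planted_rois) for (h in levels(mesh$hemisphere)) {
    verts <- which(mesh$roi == rn & mesh$hemisphere == h)
    if (length(verts)) planted_units[[paste(rn, h, sep = ".")]] <- verts
  }
  alpha_series <- with_seed(derive_seed(seed, "alpha"), {
    lapply(seq_along(planted_units), function(i)
      shaped_noise(n, fs, bandpass_amp(truth$effect_band[1], truth$effect_band[2]))$x)
  })
  alpha_out <- matrix(0, length(planted_units), n)
  for (i in seq_along(planted_units)) {
    mod <- alpha_series[[i]] * gvec
    alpha_out[i, ] <- mod
    S[planted_units[[i]], ] <- sweep(S[planted_units[[i]], , drop = FALSE], 2, mod, "+")
  }

  # --- evoked transients at each sound onset, auditory ROIs ---
  if (truth$evoked_amplitude > 0) {
    ev_verts <- which(mesh$roi %in% truth$evoked_rois)
    tmpl <- evoked_template(fs, truth$evoked_amplitude)
    onsets <- as.vector(outer(schedule$events$onset_s, schedule$sound_offsets_s, "+"))
    ev_sig <- numeric(n)
    for (t0 in onsets) ev_sig <- add_at(ev_sig, floor(t0 * fs) + 1L, tmpl)
    S[ev_verts, ] <- sweep(S[ev_verts, , drop = FALSE], 2, ev_sig, "+")
  }

  # --- project to sensors, add correlated noise ---
  Gn <- gain_normal(gain, mesh)
  X <- signal_scale * (Gn %*% S)
  L <- chol(C)
  X <- X + t(L) %*% with_seed(derive_seed(seed, "noise"),
                              matrix(stats::rnorm(ns * n), ns, n))

  # --- EOG and blink artifacts ---
  n_pairs <- nrow(schedule$events)
  artifact_epochs <- truth$artifact_epochs
  if (is.null(artifact_epochs)) {
    k <- max(0L, round(truth$artifact_frac * n_pairs))
    artifact_epochs <- with_seed(derive_seed(seed, "blinks"),
                                 sort(sample.int(n_pairs, k)))
  }
  eog <- with_seed(derive_seed(seed, "eog"), stats::rnorm(n, 0, 5))
  if (length(artifact_epochs)) {
    btmpl <- blink_template(fs)
    bpattern <- with_seed(derive_seed(seed, "blinkpat"), stats::rnorm(ns))
    bpattern <- bpattern / sqrt(sum(bpattern^2))
    for (ep in artifact_epochs) {
      # blink centered inside the sustained window [-2, -0.25] s before onset
      t0 <- schedule$events$onset_s[ep] - 1.1 - 0.2
      i0 <- floor(t0 * fs) + 1L
      eog <- add_at(eog, i0, btmpl)
      X <- add_at_matrix(X, i0, outer(bpattern * 3 / max(btmpl), btmpl))
    }
  }

  truth_realized <- truth
  truth_realized$artifact_epochs <- artifact_epochs
  truth_realized$realized_power_ratio <- r_subj
  truth_realized$condition_band_variance <- v_cond + var_bg_band
  truth_realized$background_band_variance <- var_bg_band

  out <- structure(list(sensors = X, eog = eog, fs = fs, schedule = schedule,
                        truth = truth_realized, subject_id = subject_id,
                        noise_cov_true = C),
                   class = "sensor_session")
  if (return_sources) {
    out$sources <- S
    out$planted_alpha <- alpha_out
    out$planted_units <- planted_units
  }
  out
}

add_at_matrix <- function(X, start_idx, block) {
  idx <- start_idx + seq_len(ncol(block)) - 1L
  keep <- idx >= 1L & idx <= ncol(X)
  X[, idx[keep]] <- X[, idx[keep]] + block[, keep, drop = FALSE]
  X
}

#' @export
print.sensor_session <- function(x, ...) {
  cat(sprintf("sensor_session %s: %d sensors x %d samples @ %g Hz, %d pairs (%d blink epochs)\n",
              x$subject_id, nrow(x$sensors), ncol(x$sensors), x$fs,
              nrow(x$schedule$events), length(x$truth$artifact_epochs)))
  invisible(x)
}
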